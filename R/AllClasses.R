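#' @import methods
#' @importFrom stats cor pchisq pnorm pt qnorm rnorm runif sd setNames var
#' @importFrom utils read.csv write.table combn head
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
#' @importFrom S4Vectors DataFrame
NULL

.VALUE_KINDS <- c("log2_intensity", "rnaseq", "batch_corrected", "z_scored")
.COMPARTMENTS <- c("cortex", "subcortex", "brainstem", "cerebellum")
.SEMANTICS <- c("p_value", "score", "binary_mask")

#' BrainExpression: an expression matrix with sample metadata
#'
#' A thin extension of \linkS4class{SummarizedExperiment} holding one assay
#' (\code{"expr"}: probes or genes in rows, tissue samples in columns)
#' together with a \code{valueKind} tag recording where the values sit in
#' the processing chain: raw \code{log2_intensity} microarray values,
#' \code{rnaseq} quantifications, \code{batch_corrected} values after
#' additive donor-effect removal, or \code{z_scored} values after
#' row-wise standardization. Sample annotation (donor, compartment, MNI
#' coordinates) lives in \code{colData}; probe-to-gene annotation, when
#' attached, in \code{rowData}.
#'
#' @slot valueKind character flag, one of \code{log2_intensity},
#'   \code{rnaseq}, \code{batch_corrected}, \code{z_scored}.
#' @aliases BrainExpression-class
#' @exportClass BrainExpression
setClass("BrainExpression",
    contains = "SummarizedExperiment",
    representation(valueKind = "character"))

setValidity("BrainExpression", function(object) {
    msg <- character()
    if (length(object@valueKind) != 1L ||
        !object@valueKind %in% .VALUE_KINDS)
        msg <- c(msg, sprintf("valueKind must be one of: %s",
                              paste(.VALUE_KINDS, collapse = ", ")))
    m <- SummarizedExperiment::assay(object, withDimnames = FALSE)
    if (!is.numeric(m) || anyNA(m) || any(!is.finite(m)))
        msg <- c(msg, "expression values must be finite and non-missing")
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "row identifiers must be present and unique")
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
        msg <- c(msg, "column (sample) identifiers must be present and unique")
    if (length(msg)) msg else TRUE
})

#' Construct a BrainExpression object
#'
#' @param values numeric matrix, rows = probes or genes, columns = samples;
#'   must carry unique dimnames.
#' @param valueKind one of \code{"log2_intensity"}, \code{"rnaseq"},
#'   \code{"batch_corrected"}, \code{"z_scored"}.
#' @param sampleInfo optional data.frame of per-sample annotation aligned to
#'   the columns (matched by \code{sample_id} when present).
#' @param probeInfo optional data.frame of per-row annotation.
#' @return A \linkS4class{BrainExpression} object.
#' @examples
#' m <- matrix(rnorm(6), 2, 3,
#'             dimnames = list(c("p1", "p2"), c("s1", "s2", "s3")))
#' be <- BrainExpression(m, "log2_intensity")
#' valueKind(be)
#' @export
BrainExpression <- function(values, valueKind = "log2_intensity",
                            sampleInfo = NULL, probeInfo = NULL) {
    values <- as.matrix(values)
    storage.mode(values) <- "double"
    cd <- if (is.null(sampleInfo)) {
        S4Vectors::DataFrame(row.names = colnames(values))
    } else {
        si <- as.data.frame(sampleInfo)
        if ("sample_id" %in% names(si)) {
            idx <- match(colnames(values), si$sample_id)
            if (anyNA(idx))
                stop("sampleInfo lacks annotation for samples: ",
                     paste(colnames(values)[is.na(idx)], collapse = ", "))
            si <- si[idx, , drop = FALSE]
        }
        rownames(si) <- colnames(values)
        S4Vectors::DataFrame(si)
    }
    rd <- if (is.null(probeInfo)) {
        S4Vectors::DataFrame(row.names = rownames(values))
    } else {
        pi_ <- as.data.frame(probeInfo)
        rownames(pi_) <- rownames(values)
        S4Vectors::DataFrame(pi_)
    }
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(expr = values), colData = cd, rowData = rd)
    new("BrainExpression", se, valueKind = valueKind)
}

#' StatVolume: a 3-D statistic volume with a world-space affine
#'
#' Holds a scalar grid indexed (i, j, k), the 4x4 affine mapping 0-based
#' homogeneous voxel indices to MNI mm coordinates, and a semantics tag:
#' \code{p_value} (voxelwise significance, thresholded below alpha; stored
#' zeros are background outside the analysis mask, not p = 0),
#' \code{score} (larger = more significant), or \code{binary_mask}.
#'
#' @slot grid 3-D numeric array.
#' @slot affine 4x4 invertible matrix, voxel (0-based) to mm.
#' @slot semantics one of \code{p_value}, \code{score}, \code{binary_mask}.
#' @aliases StatVolume-class
#' @exportClass StatVolume
setClass("StatVolume",
    representation(grid = "array", affine = "matrix",
                   semantics = "character"))

setValidity("StatVolume", function(object) {
    msg <- character()
    if (length(dim(object@grid)) != 3L)
        msg <- c(msg, "grid must be a 3-D array")
    if (!identical(dim(object@affine), c(4L, 4L)))
        msg <- c(msg, "affine must be 4x4")
    else if (abs(det(object@affine)) < .Machine$double.eps * 64)
        msg <- c(msg, "affine must be invertible")
    if (length(object@semantics) != 1L ||
        !object@semantics %in% .SEMANTICS)
        msg <- c(msg, sprintf("semantics must be one of: %s",
                              paste(.SEMANTICS, collapse = ", ")))
    g <- object@grid[is.finite(object@grid)]
    if (identical(object@semantics, "p_value") &&
        (any(g < 0) || any(g > 1)))
        msg <- c(msg, "p_value grid entries must lie in [0, 1]")
    if (identical(object@semantics, "binary_mask") && !all(g %in% c(0, 1)))
        msg <- c(msg, "binary_mask grid entries must be 0 or 1")
    if (length(msg)) msg else TRUE
})

#' Construct a StatVolume
#'
#' @param grid 3-D numeric array of voxel values.
#' @param affine 4x4 matrix mapping 0-based voxel indices (homogeneous) to
#'   world mm.
#' @param semantics \code{"p_value"}, \code{"score"} or \code{"binary_mask"}.
#' @return A \linkS4class{StatVolume}.
#' @export
StatVolume <- function(grid, affine, semantics = "p_value") {
    new("StatVolume", grid = grid, affine = affine, semantics = semantics)
}

#' CorrelationComparison: paired correlation structure of two sample groups
#'
#' Result container for the differential co-expression contrast: Pearson
#' correlation matrices of the same genes in two disjoint sample groups
#' (affected vs unaffected), per-pair correlation p-values, the Steiger
#' chi-square test of matrix equality, and per-pair two-sample Fisher
#' r-to-z contrasts for the retained focus-gene pairs.
#'
#' @slot genes character vector, gene order shared by both matrices.
#' @slot Raffected,Runaffected symmetric unit-diagonal correlation matrices.
#' @slot n1,n2 group sizes (affected, unaffected).
#' @slot pairPAffected,pairPUnaffected Bonferroni-corrected two-sided
#'   per-pair correlation p-values (NA on the diagonal).
#' @slot steiger list with \code{chi2}, \code{df}, \code{p}.
#' @slot fisher data.frame of retained pairs: gene pair, r in both groups,
#'   z statistic, raw and Bonferroni p.
#' @slot focusGene the gene whose pairs were contrasted.
#' @slot filterRule pair retention rule used (\code{"either"}/\code{"both"}).
#' @aliases CorrelationComparison-class
#' @exportClass CorrelationComparison
setClass("CorrelationComparison",
    representation(genes = "character", Raffected = "matrix",
                   Runaffected = "matrix", n1 = "integer", n2 = "integer",
                   pairPAffected = "matrix", pairPUnaffected = "matrix",
                   steiger = "list", fisher = "data.frame",
                   focusGene = "character", filterRule = "character"))

setValidity("CorrelationComparison", function(object) {
    k <- length(object@genes)
    msg <- character()
    for (nm in c("Raffected", "Runaffected")) {
        R <- slot(object, nm)
        if (!identical(dim(R), c(k, k)))
            msg <- c(msg, sprintf("%s must be %d x %d", nm, k, k))
        else {
            if (max(abs(R - t(R))) > 1e-12)
                msg <- c(msg, sprintf("%s must be symmetric", nm))
            if (max(abs(diag(R) - 1)) > 1e-12)
                msg <- c(msg, sprintf("%s must have unit diagonal", nm))
            if (any(abs(R) > 1 + 1e-12))
                msg <- c(msg, sprintf("%s entries must satisfy |r| <= 1", nm))
        }
    }
    if (!identical(object@steiger$df, as.integer(k * (k - 1) / 2)))
        msg <- c(msg, "steiger df must equal k(k-1)/2")
    if (length(msg)) msg else TRUE
})
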