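#' Accessors for oxtmap classes
#'
#' \code{valueKind} returns the processing-stage tag of a
#' \linkS4class{BrainExpression}; \code{exprValues} its assay matrix;
#' \code{sampleInfo} its per-sample annotation as a plain data.frame.
#' \code{statGrid}, \code{statAffine} and \code{statSemantics} expose the
#' components of a \linkS4class{StatVolume}.
#'
#' @param x a BrainExpression or StatVolume object.
#' @return The corresponding component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("valueKind", function(x) standardGeneric("valueKind"))
#' @rdname accessors
#' @export
setMethod("valueKind", "BrainExpression", function(x) x@valueKind)

#' @rdname accessors
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))
#' @rdname accessors
#' @export
setMethod("exprValues", "BrainExpression", function(x)
    SummarizedExperiment::assay(x, "expr"))

#' @rdname accessors
#' @export
setGeneric("sampleInfo", function(x) standardGeneric("sampleInfo"))
#' @rdname accessors
#' @export
setMethod("sampleInfo", "BrainExpression", function(x)
    as.data.frame(SummarizedExperiment::colData(x)))

#' @rdname accessors
#' @export
setGeneric("statGrid", function(x) standardGeneric("statGrid"))
#' @rdname accessors
#' @export
setMethod("statGrid", "StatVolume", function(x) x@grid)

#' @rdname accessors
#' @export
setGeneric("statAffine", function(x) standardGeneric("statAffine"))
#' @rdname accessors
#' @export
setMethod("statAffine", "StatVolume", function(x) x@affine)

#' @rdname accessors
#' @export
setGeneric("statSemantics", function(x) standardGeneric("statSemantics"))
#' @rdname accessors
#' @export
setMethod("statSemantics", "StatVolume", function(x) x@semantics)

setMethod("show", "BrainExpression", function(object) {
    cat("BrainExpression:", nrow(object), "features x", ncol(object),
        "samples\n")
    cat("  valueKind:", object@valueKind, "\n")
    cd <- SummarizedExperiment::colData(object)
    if (ncol(cd))
        cat("  sample annotation:", paste(colnames(cd), collapse = ", "),
            "\n")
    rd <- SummarizedExperiment::rowData(object)
    if (ncol(rd))
        cat("  feature annotation:", paste(colnames(rd), collapse = ", "),
            "\n")
})

setMethod("show", "StatVolume", function(object) {
    d <- dim(object@grid)
    cat(sprintf("StatVolume: %d x %d x %d voxels, semantics = %s\n",
                d[1], d[2], d[3], object@semantics))
    vs <- sqrt(colSums(object@affine[1:3, 1:3]^2))
    cat(sprintf("  voxel size (mm): %.3g x %.3g x %.3g\n",
                vs[1], vs[2], vs[3]))
})

setMethod("show", "CorrelationComparison", function(object) {
    k <- length(object@genes)
    cat(sprintf(
        "CorrelationComparison: %d genes, n = %d (affected) vs %d (unaffected)\n",
        k, object@n1, object@n2))
    cat(sprintf("  Steiger chi2 = %.4g on %d df, p = %.3g\n",
                object@steiger$chi2, object@steiger$df, object@steiger$p))
    cat(sprintf("  focus gene %s: %d retained pair(s) [filter: %s]\n",
                object@focusGene, nrow(object@fisher), object@filterRule))
    if (nrow(object@fisher)) {
        sig <- object@fisher$p_bonf < 0.05
        cat(sprintf("  significant contrasts (corrected p < 0.05): %d\n",
                    sum(sig)))
    }
})
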