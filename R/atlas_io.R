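## Tabular and volumetric input/output. No statistics here.

.detect_delim <- function(path) {
    first <- readLines(path, n = 1L)
    if (grepl("\t", first)) "\t" else ","
}

#' Read a sample annotation table
#'
#' Loads an atlas-style sample annotation file (one row per tissue sample)
#' with columns \code{sample_id} (or \code{well_id}), \code{donor_id},
#' \code{structure_acronym}, optional \code{structure_name}, MNI world
#' coordinates \code{mni_x}, \code{mni_y}, \code{mni_z} (mm), and either an
#' explicit \code{compartment} column or a caller-supplied lookup from
#' structure acronym to compartment. Compartment is one of \code{cortex},
#' \code{subcortex}, \code{brainstem}, \code{cerebellum}. Delimiter is
#' auto-detected among comma and tab.
#'
#' @param path path to a CSV/TSV file with a header row.
#' @param compartmentLookup optional data.frame with columns
#'   \code{structure_acronym} and \code{compartment}, used when the table
#'   has no explicit \code{compartment} column.
#' @return data.frame of sample records in file order with columns
#'   \code{sample_id}, \code{donor_id}, \code{structure_acronym},
#'   \code{structure_name}, \code{compartment}, \code{mni_x}, \code{mni_y},
#'   \code{mni_z}.
#' @export
readSamples <- function(path, compartmentLookup = NULL) {
    if (!file.exists(path)) stop("sample table not found: ", path)
    df <- read.csv(path, sep = .detect_delim(path), check.names = FALSE,
                   stringsAsFactors = FALSE)
    if (!"sample_id" %in% names(df) && "well_id" %in% names(df))
        df$sample_id <- as.character(df$well_id)
    required <- c("sample_id", "donor_id", "structure_acronym",
                  "mni_x", "mni_y", "mni_z")
    missing <- setdiff(required, names(df))
    if (length(missing))
        stop("sample table is missing required column(s): ",
             paste(missing, collapse = ", "))
    df$sample_id <- as.character(df$sample_id)
    df$donor_id <- as.character(df$donor_id)
    if (anyDuplicated(df$sample_id))
        stop("duplicate sample_id in sample table")
    for (cc in c("mni_x", "mni_y", "mni_z")) {
        v <- suppressWarnings(as.numeric(df[[cc]]))
        if (anyNA(v) || any(!is.finite(v)))
            stop("non-finite coordinate value(s) in column ", cc)
        df[[cc]] <- v
    }
    if (!"structure_name" %in% names(df)) df$structure_name <- ""
    if (!"compartment" %in% names(df)) {
        if (is.null(compartmentLookup))
            stop("no compartment column and no compartmentLookup supplied")
        idx <- match(df$structure_acronym,
                     compartmentLookup$structure_acronym)
        if (anyNA(idx))
            stop("structure acronym(s) not in compartment lookup: ",
                 paste(unique(df$structure_acronym[is.na(idx)]),
                       collapse = ", "))
        df$compartment <- as.character(compartmentLookup$compartment[idx])
    }
    bad <- setdiff(unique(df$compartment), .COMPARTMENTS)
    if (length(bad))
        stop("unknown compartment value(s): ", paste(bad, collapse = ", "))
    df[, c("sample_id", "donor_id", "structure_acronym", "structure_name",
           "compartment", "mni_x", "mni_y", "mni_z")]
}

#' Write a sample annotation table
#'
#' @param samples data.frame as returned by \code{\link{readSamples}}.
#' @param path output CSV path.
#' @export
writeSamples <- function(samples, path) {
    write.csv2_ <- function(x, p)
        write.table(x, p, sep = ",", row.names = FALSE, quote = FALSE)
    write.csv2_(samples, path)
    invisible(path)
}

#' Read an expression matrix
#'
#' Loads a rectangular delimited table with feature identifiers in the
#' first column and sample identifiers in the header into a
#' \linkS4class{BrainExpression} object. Duplicate identifiers,
#' non-numeric cells or missing values raise an error.
#'
#' @param path path to a CSV/TSV file.
#' @param valueKind value-kind tag, \code{"log2_intensity"} by default;
#'   use \code{"rnaseq"} for RNA-seq companion matrices.
#' @return A \linkS4class{BrainExpression}.
#' @export
readExpression <- function(path, valueKind = "log2_intensity") {
    if (!file.exists(path)) stop("expression table not found: ", path)
    df <- read.csv(path, sep = .detect_delim(path), check.names = FALSE,
                   stringsAsFactors = FALSE)
    ids <- as.character(df[[1]])
    if (anyDuplicated(ids)) stop("duplicate row identifier(s): ",
        paste(unique(ids[duplicated(ids)]), collapse = ", "))
    m <- as.matrix(df[, -1, drop = FALSE])
    if (anyDuplicated(colnames(m))) stop("duplicate column identifier(s)")
    suppressWarnings(storage.mode(m) <- "double")
    if (anyNA(m) || any(!is.finite(m)))
        stop("expression table contains missing or non-numeric cells")
    rownames(m) <- ids
    BrainExpression(m, valueKind = valueKind)
}

#' Write an expression matrix
#'
#' Values are written in decimal text at 6 significant digits, so a
#' write/read cycle reproduces the file byte-identically.
#'
#' @param expr a \linkS4class{BrainExpression} or numeric matrix.
#' @param path output CSV path.
#' @export
writeExpression <- function(expr, path) {
    m <- if (is(expr, "BrainExpression")) exprValues(expr) else expr
    df <- data.frame(id = rownames(m), signif(m, 6), check.names = FALSE)
    write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Read a statistic volume from NIfTI-1
#'
#' @param path path to a 3-D \code{.nii} or \code{.nii.gz} file.
#' @param semantics declared polarity of the stored values (the file does
#'   not self-describe it): \code{"p_value"}, \code{"score"} or
#'   \code{"binary_mask"}.
#' @return A \linkS4class{StatVolume}; the affine maps 0-based voxel
#'   indices to world mm, as stored in the file's sform/qform.
#' @export
readStatVolume <- function(path, semantics = "p_value") {
    if (!file.exists(path)) stop("volume not found: ", path)
    img <- RNifti::readNifti(path)
    d <- dim(img)
    if (length(d) == 4L && d[4] == 1L) dim(img) <- d[1:3]
    if (length(dim(img)) != 3L)
        stop("expected a 3-D volume, got ", length(d), " dimensions")
    aff <- unclass(RNifti::xform(img))
    attributes(aff) <- list(dim = c(4L, 4L))
    StatVolume(grid = array(as.numeric(img), dim = dim(img)),
               affine = aff, semantics = semantics)
}

#' Write a statistic volume to NIfTI-1
#'
#' @param vol a \linkS4class{StatVolume}.
#' @param path output path (\code{.nii} or \code{.nii.gz}).
#' @export
writeStatVolume <- function(vol, path) {
    img <- RNifti::asNifti(statGrid(vol), datatype = "double")
    img <- RNifti::`sform<-`(img, structure(statAffine(vol), code = 2L))
    RNifti::writeNifti(img, path)
    invisible(path)
}

.DE_COLUMNS <- c("map_name", "compartment", "gene", "n_affected",
                 "n_unaffected", "rank_sum_U", "mean_diff_z", "p_raw",
                 "m_tests", "p_bonf", "significant", "untestable")

.PAIR_COLUMNS <- c("map_name", "compartment", "gene_a", "gene_b",
                   "r_affected", "r_unaffected", "z_stat", "p_raw",
                   "m_pairs", "p_bonf", "significant")

.fmt_table <- function(df, columns) {
    if (is.null(df) || !nrow(df)) {
        df <- as.data.frame(setNames(rep(list(character(0)),
                                         length(columns)), columns))
    } else {
        missing <- setdiff(columns, names(df))
        for (cc in missing) df[[cc]] <- NA
        df <- df[, columns, drop = FALSE]
        num <- vapply(df, is.numeric, logical(1))
        df[num] <- lapply(df[num], function(v) signif(v, 8))
    }
    df
}

#' Write result tables
#'
#' Writes the differential-expression table
#' (\code{differential_expression.tsv}), the pairwise co-expression
#' contrast table (\code{coexpression_pairs.tsv}), the classification audit
#' table(s) and a machine-readable JSON summary into \code{outDir}.
#' Column order is fixed and numeric values are rounded to 8 significant
#' digits, so re-running on identical inputs reproduces the files
#' byte-identically.
#'
#' @param results list with optional elements \code{differential}
#'   (data.frame), \code{pairs} (data.frame), \code{classification}
#'   (data.frame or named list of data.frames, one per map) and
#'   \code{summary} (list, serialized as JSON).
#' @param outDir output directory, created if needed.
#' @return invisibly, the paths written.
#' @export
writeResults <- function(results, outDir) {
    if (!dir.exists(outDir) &&
        !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
        stop("cannot create output directory: ", outDir)
    paths <- character()
    wr <- function(df, name) {
        p <- file.path(outDir, name)
        write.table(df, p, sep = "\t", row.names = FALSE, quote = FALSE)
        p
    }
    paths <- c(paths, wr(.fmt_table(results$differential, .DE_COLUMNS),
                         "differential_expression.tsv"))
    paths <- c(paths, wr(.fmt_table(results$pairs, .PAIR_COLUMNS),
                         "coexpression_pairs.tsv"))
    cls <- results$classification
    if (!is.null(cls)) {
        if (is.data.frame(cls)) cls <- list(classification = cls)
        for (nm in names(cls)) {
            audit <- cls[[nm]]
            num <- vapply(audit, is.numeric, logical(1))
            audit[num] <- lapply(audit[num], function(v) signif(v, 8))
            paths <- c(paths, wr(audit,
                                 sprintf("classification_%s.tsv", nm)))
        }
    }
    sm <- if (is.null(results$summary)) list() else results$summary
    p <- file.path(outDir, "summary.json")
    jsonlite::write_json(sm, p, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
    paths <- c(paths, p)
    invisible(paths)
}
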