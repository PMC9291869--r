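## Donor (batch) correction and z-normalization. The pipeline order is
## fixed: batch correction -> z-normalization -> group statistics.

#' Remove additive donor effects
#'
#' Fits, per row, the additive model
#' \deqn{x_{gs} = \mu_g + \beta_{g,d(s)} + \varepsilon_{gs}}
#' with donor offsets constrained to sum to zero weighted by donor sample
#' counts, and subtracts the fitted offset from each entry. For a single
#' factor this is simply subtracting each donor's row mean and adding back
#' the row's grand mean, so after correction every donor's per-row mean
#' equals the row's grand mean and the grand mean itself is preserved.
#'
#' @param expr \linkS4class{BrainExpression} with \code{valueKind}
#'   \code{"log2_intensity"} (or \code{"rnaseq"}).
#' @param donors character vector of donor ids, one per column; defaults
#'   to the \code{donor_id} column of \code{sampleInfo(expr)}.
#' @return \linkS4class{BrainExpression} with \code{valueKind}
#'   \code{"batch_corrected"}. A single-donor matrix is returned
#'   unchanged (up to the tag).
#' @export
removeDonorEffects <- function(expr, donors = NULL) {
    if (is.null(donors)) {
        si <- sampleInfo(expr)
        if (!"donor_id" %in% names(si))
            stop("no donors given and no donor_id annotation on expr")
        donors <- si$donor_id
    }
    m <- exprValues(expr)
    if (length(donors) != ncol(m))
        stop("need one donor id per expression column")
    donors <- as.character(donors)
    f <- factor(donors)
    out <- m
    if (nlevels(f) > 1L) {
        grand <- rowMeans(m)
        for (lev in levels(f)) {
            idx <- which(f == lev)
            offs <- rowMeans(m[, idx, drop = FALSE]) - grand
            out[, idx] <- m[, idx, drop = FALSE] - offs
        }
    }
    BrainExpression(out, valueKind = "batch_corrected",
                    sampleInfo = sampleInfo(expr))
}

#' Z-normalize expression across samples
#'
#' Standardizes each row over all retained samples jointly (both
#' compartments, affected and unaffected pooled): subtract the row mean
#' and divide by the sample standard deviation (denominator n - 1).
#'
#' @param expr \linkS4class{BrainExpression}, normally
#'   \code{batch_corrected}.
#' @return \linkS4class{BrainExpression} with \code{valueKind}
#'   \code{"z_scored"}; each row has mean 0 and sd 1.
#' @export
zNormalize <- function(expr) {
    m <- exprValues(expr)
    if (ncol(m) < 2L) stop("need at least 2 samples to z-normalize")
    mu <- rowMeans(m)
    s <- apply(m, 1L, sd)
    zero <- s == 0
    if (any(zero))
        stop("zero-variance row(s): ",
             paste(rownames(m)[zero], collapse = ", "))
    BrainExpression((m - mu) / s, valueKind = "z_scored",
                    sampleInfo = sampleInfo(expr))
}

#' Drop the columns of given donors
#'
#' Used for the male-only analysis path: the female donor's samples are
#' removed \emph{before} batch correction and normalization.
#'
#' @param expr \linkS4class{BrainExpression} with donor annotation.
#' @param dropDonors donor ids to remove.
#' @return \linkS4class{BrainExpression} restricted to the other donors.
#' @export
dropDonorColumns <- function(expr, dropDonors) {
    si <- sampleInfo(expr)
    if (!"donor_id" %in% names(si))
        stop("expr carries no donor annotation")
    keep <- !si$donor_id %in% dropDonors
    if (!any(keep)) stop("dropping these donors would leave no samples")
    m <- exprValues(expr)[, keep, drop = FALSE]
    BrainExpression(m, valueKind = valueKind(expr),
                    sampleInfo = si[keep, , drop = FALSE])
}
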