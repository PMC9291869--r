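## Point-sample-to-voxel mapping: threshold statistic volumes and classify
## each tissue sample as affected/unaffected by trilinear interpolation of
## the volume at the sample's MNI coordinate.

#' Threshold a statistic volume into a binary mask
#'
#' For \code{p_value} semantics a voxel enters the mask iff
#' \code{0 < value < alpha}; stored zeros are background outside the
#' analysis mask, never p = 0. For \code{score} semantics (larger = more
#' significant, e.g. 1 - p) a voxel enters iff \code{value > cutoff}.
#'
#' @param vol \linkS4class{StatVolume} with \code{p_value} or \code{score}
#'   semantics.
#' @param alpha significance level in (0, 1); default 0.05.
#' @param cutoff score cutoff equivalent to \code{alpha}; defaults to
#'   \code{1 - alpha} (a map storing 1 - p).
#' @return \linkS4class{StatVolume} with \code{binary_mask} semantics on
#'   the same grid and affine.
#' @export
thresholdMap <- function(vol, alpha = 0.05, cutoff = 1 - alpha) {
    if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
        stop("alpha must lie in (0, 1)")
    sem <- statSemantics(vol)
    if (!sem %in% c("p_value", "score"))
        stop("cannot threshold a volume with semantics ", sem)
    g <- statGrid(vol)
    mask <- if (sem == "p_value") (g > 0 & g < alpha) else (g > cutoff)
    StatVolume(grid = array(as.numeric(mask), dim = dim(g)),
               affine = statAffine(vol), semantics = "binary_mask")
}

#' Sample a volume at world coordinates by trilinear interpolation
#'
#' Maps each MNI mm coordinate through the inverse affine to continuous
#' 0-based voxel coordinates and returns the trilinear blend of the 8
#' surrounding voxel values. Points outside the grid's support (any voxel
#' coordinate below 0 or above dim - 1) return 0 and are flagged in the
#' \code{"outside"} attribute.
#'
#' @param vol \linkS4class{StatVolume}.
#' @param mni numeric vector of length 3, or an n x 3 matrix of world
#'   coordinates in mm.
#' @return numeric vector of interpolated values (attribute
#'   \code{"outside"}: logical vector flagging out-of-volume points).
#' @export
trilinearSample <- function(vol, mni) {
    if (is.null(dim(mni))) mni <- matrix(mni, ncol = 3)
    if (ncol(mni) != 3L) stop("mni must have 3 columns (x, y, z)")
    if (any(!is.finite(mni))) stop("non-finite coordinate")
    g <- statGrid(vol)
    d <- dim(g)
    inv <- solve(statAffine(vol))
    vox <- t(inv %*% rbind(t(mni), 1))[, 1:3, drop = FALSE]
    n <- nrow(vox)
    out <- numeric(n)
    outside <- logical(n)
    for (s in seq_len(n)) {
        v <- vox[s, ]
        if (any(v < 0) || any(v > d - 1)) {
            outside[s] <- TRUE
            next
        }
        i0 <- pmin(floor(v), d - 2)  # keep an upper neighbor at the edge
        i0 <- pmax(i0, 0)
        w <- v - i0                  # fractional offsets in [0, 1]
        acc <- 0
        for (corner in 0:7) {
            cx <- bitwAnd(corner, 1L)
            cy <- bitwAnd(bitwShiftR(corner, 1L), 1L)
            cz <- bitwAnd(bitwShiftR(corner, 2L), 1L)
            wt <- (if (cx) w[1] else 1 - w[1]) *
                  (if (cy) w[2] else 1 - w[2]) *
                  (if (cz) w[3] else 1 - w[3])
            if (wt != 0)
                acc <- acc + wt * g[i0[1] + cx + 1, i0[2] + cy + 1,
                                    i0[3] + cz + 1]
        }
        out[s] <- acc
    }
    attr(out, "outside") <- outside
    out
}

#' Classify samples as affected or unaffected
#'
#' Brainstem and cerebellum samples are excluded up front; samples whose
#' coordinate falls outside the volume's support are excluded with reason
#' \code{outside-volume} (never silently labeled unaffected). The
#' remaining cortical/subcortical samples are labeled \code{affected}
#' when, under the default mode \code{interpolate_then_threshold}, the
#' trilinearly interpolated continuous statistic passes the alpha
#' criterion (for \code{p_value} semantics: 0 < value < alpha; for
#' \code{score}: value > cutoff), or, under
#' \code{threshold_then_interpolate}, when the interpolated binary mask
#' value exceeds \code{membershipCutoff} (default 0: any overlap with the
#' mask counts as falling inside it).
#'
#' @param samples data.frame from \code{\link{readSamples}}.
#' @param vol \linkS4class{StatVolume} (\code{p_value}, \code{score} or,
#'   for mode B, an already thresholded \code{binary_mask}).
#' @param mode \code{"interpolate_then_threshold"} (default) or
#'   \code{"threshold_then_interpolate"}.
#' @param alpha significance level applied to the interpolated statistic.
#' @param cutoff score cutoff for \code{score} semantics.
#' @param membershipCutoff mask-membership cutoff for mode B.
#' @return data.frame, one row per input sample: \code{sample_id},
#'   \code{compartment}, \code{interp_value}, \code{label} (affected/
#'   unaffected, NA when excluded), \code{excluded},
#'   \code{excluded_reason}.
#' @export
classifySamples <- function(samples, vol,
                            mode = c("interpolate_then_threshold",
                                     "threshold_then_interpolate"),
                            alpha = 0.05, cutoff = 1 - alpha,
                            membershipCutoff = 0) {
    mode <- match.arg(mode)
    stopifnot(is.data.frame(samples))
    if (!all(samples$compartment %in% .COMPARTMENTS))
        stop("unresolved compartment(s) in sample table")
    svol <- vol
    if (mode == "threshold_then_interpolate" &&
        statSemantics(vol) != "binary_mask")
        svol <- thresholdMap(vol, alpha = alpha, cutoff = cutoff)
    coords <- as.matrix(samples[, c("mni_x", "mni_y", "mni_z")])
    val <- trilinearSample(svol, coords)
    outside <- attr(val, "outside")
    attributes(val) <- NULL

    excluded <- samples$compartment %in% c("brainstem", "cerebellum")
    reason <- ifelse(excluded, samples$compartment, "")
    oow <- !excluded & outside
    excluded <- excluded | oow
    reason[oow] <- "outside-volume"

    affected <- if (mode == "interpolate_then_threshold") {
        switch(statSemantics(svol),
               p_value = val > 0 & val < alpha,
               score = val > cutoff,
               binary_mask = val > membershipCutoff)
    } else {
        val > membershipCutoff
    }
    label <- ifelse(excluded, NA_character_,
                    ifelse(affected, "affected", "unaffected"))
    data.frame(sample_id = samples$sample_id,
               compartment = samples$compartment,
               interp_value = val, label = label, excluded = excluded,
               excluded_reason = reason, stringsAsFactors = FALSE)
}

#' Tabulate classifications by compartment and label
#'
#' @param cls data.frame from \code{\link{classifySamples}}.
#' @return 2 x 2 integer matrix, rows = (subcortex, cortex), columns =
#'   (affected, unaffected); excluded samples are not counted.
#' @export
countByGroup <- function(cls) {
    keep <- cls[!cls$excluded, , drop = FALSE]
    tab <- matrix(0L, 2, 2,
                  dimnames = list(c("subcortex", "cortex"),
                                  c("affected", "unaffected")))
    for (comp in rownames(tab))
        for (lab in colnames(tab))
            tab[comp, lab] <- sum(keep$compartment == comp &
                                  keep$label == lab)
    tab
}
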