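## Synthetic atlas emulator: multi-donor samples scattered in a volume
## with cortical/subcortical/excluded compartments, probe-level expression
## with planted affected-region effects and planted in-region gene-gene
## correlation, an RNA-seq companion for two donors, and a p-statistic
## volume containing suprathreshold clusters. All randomness flows from
## the single seed in the config.

.DEFAULT_GENES <- c("OXT", "OXTR", "CD38", "AVPR1A", "AVPR1B", "AVPR2")

#' Synthetic dataset configuration
#'
#' Defines the study conditions emulated by \code{\link{generateDataset}}.
#' Defaults mirror the scale of a six-donor whole-brain atlas crossed with
#' one thresholded statistic map: 986 subcortical and 1762 cortical
#' samples of which 180 and 140 respectively fall inside suprathreshold
#' clusters, 150 brainstem/cerebellum samples, six oxytocin-pathway genes
#' with three probes each, an affected-region expression effect of 1 z-unit
#' on \code{OXTR} (0.5 on \code{OXT} and \code{CD38}), and an
#' affected-only \code{OXTR}-\code{AVPR1A} co-expression of r = 0.4.
#'
#' @param seed integer seed driving all randomness.
#' @param nDonors number of donors; the last one is tagged female.
#' @param volumeShape integer triple (i, j, k) of the statistic grid.
#' @param voxelSizeMm isotropic voxel edge in mm.
#' @param nSubcortical,nCortical,nExcluded sample counts per compartment
#'   (excluded = brainstem + cerebellum).
#' @param clusters data.frame of suprathreshold spheres: columns
#'   \code{x, y, z} (center mm), \code{radius_mm}, \code{compartment},
#'   \code{n_samples} (samples planted inside).
#' @param genes gene symbols.
#' @param probesPerGene probes annotated to each gene.
#' @param effectZ named vector: planted affected-vs-unaffected expression
#'   difference per gene, in units of the final z-scored scale.
#' @param coexprEffect data.frame with columns \code{gene_a},
#'   \code{gene_b}, \code{r} planting a within-cluster correlation.
#' @param donorOffsetSd sd of per-donor, per-gene additive batch offsets.
#' @param noiseSd residual sd of the gene-level signal.
#' @param pFloor p-value written into cluster voxels (background voxels
#'   inside the brain support hold 1.0; outside, 0).
#' @return list of class \code{"syntheticConfig"}.
#' @export
syntheticConfig <- function(seed = 1L, nDonors = 6L,
                            volumeShape = c(40L, 48L, 40L),
                            voxelSizeMm = 4,
                            nSubcortical = 986L, nCortical = 1762L,
                            nExcluded = 150L,
                            clusters = NULL,
                            genes = .DEFAULT_GENES,
                            probesPerGene = 3L,
                            effectZ = c(OXT = 0.5, OXTR = 1.0, CD38 = 0.5,
                                        AVPR1A = 0, AVPR1B = 0, AVPR2 = 0),
                            coexprEffect = data.frame(
                                gene_a = "OXTR", gene_b = "AVPR1A",
                                r = 0.4),
                            donorOffsetSd = 1, noiseSd = 1,
                            pFloor = 0.01) {
    if (is.null(clusters))
        clusters <- data.frame(
            x = c(10, -35), y = c(0, -35), z = c(0, 25),
            radius_mm = c(16, 16),
            compartment = c("subcortex", "cortex"),
            n_samples = c(180L, 140L))
    stopifnot(all(clusters$radius_mm > 0),
              is.null(coexprEffect) || all(abs(coexprEffect$r) < 1),
              nSubcortical >= 0, nCortical >= 0, nExcluded >= 0)
    full <- setNames(rep(0, length(genes)), genes)
    full[names(effectZ)] <- effectZ
    cfg <- list(seed = as.integer(seed), nDonors = as.integer(nDonors),
                volumeShape = as.integer(volumeShape),
                voxelSizeMm = voxelSizeMm,
                nSubcortical = as.integer(nSubcortical),
                nCortical = as.integer(nCortical),
                nExcluded = as.integer(nExcluded),
                clusters = clusters, genes = genes,
                probesPerGene = as.integer(probesPerGene),
                effectZ = full, coexprEffect = coexprEffect,
                donorOffsetSd = donorOffsetSd, noiseSd = noiseSd,
                pFloor = pFloor)
    extent <- (cfg$volumeShape - 1) * voxelSizeMm / 2
    for (i in seq_len(nrow(clusters))) {
        ctr <- as.numeric(clusters[i, c("x", "y", "z")])
        if (any(abs(ctr) + clusters$radius_mm[i] > extent))
            stop("cluster ", i, " extends outside the volume")
    }
    class(cfg) <- "syntheticConfig"
    cfg
}

.volume_affine <- function(cfg) {
    aff <- diag(c(rep(cfg$voxelSizeMm, 3), 1))
    aff[1:3, 4] <- -(cfg$volumeShape - 1) * cfg$voxelSizeMm / 2
    aff
}

## semi-axes of the ellipsoidal brain support, mm
.support_axes <- function(cfg)
    0.45 * (cfg$volumeShape - 1) * cfg$voxelSizeMm

.unit_dirs <- function(n) {
    v <- matrix(rnorm(3 * n), ncol = 3)
    v / sqrt(rowSums(v^2))
}

## uniform draws inside a ball
.runif_ball <- function(n, center, radius) {
    r <- radius * runif(n)^(1 / 3)
    sweep(.unit_dirs(n) * r, 2, center, `+`)
}

## draw n points from `draw(k)` subject to being farther than
## radius + margin from every cluster center
.draw_avoiding <- function(n, draw, clusters, margin) {
    out <- matrix(numeric(0), ncol = 3)
    guard <- 0L
    while (nrow(out) < n) {
        pts <- draw(max(2L * n, 64L))
        ok <- rep(TRUE, nrow(pts))
        for (i in seq_len(nrow(clusters))) {
            ctr <- as.numeric(clusters[i, c("x", "y", "z")])
            dd <- sqrt(rowSums(sweep(pts, 2, ctr)^2))
            ok <- ok & dd > clusters$radius_mm[i] + margin
        }
        out <- rbind(out, pts[ok, , drop = FALSE])
        guard <- guard + 1L
        if (guard > 200L)
            stop("cannot place samples outside clusters; region too full")
    }
    out[seq_len(n), , drop = FALSE]
}

#' Generate a synthetic imaging-transcriptomics dataset
#'
#' Builds, from one seed, (1) a sample table with donors, compartments and
#' MNI coordinates, where each cluster's planted samples lie at least two
#' voxels inside its boundary and all other samples at least two voxels
#' outside every cluster, so sphere membership is unambiguous under
#' trilinear interpolation; (2) a probe-level log2-intensity matrix built
#' as gene signal + donor offset + probe offset + probe noise, where the
#' gene signal carries the planted in-cluster mean shift and a shared
#' latent factor inducing the planted in-cluster correlations; (3) an
#' RNA-seq companion for the first two donors, a strictly monotone
#' transform of the gene signal; (4) a p-statistic volume holding
#' \code{pFloor} in cluster voxels, 1.0 elsewhere inside an ellipsoidal
#' brain support, 0 outside it; and (5) a ground-truth record.
#'
#' The planted mean shift is calibrated so that, after donor correction
#' and global z-normalization, the expected affected-minus-unaffected
#' difference equals \code{effectZ} in z-units; the latent-factor loading
#' is \eqn{\sigma \sqrt{r/(1-r)}}, giving an in-cluster correlation of r.
#'
#' @param cfg a \code{\link{syntheticConfig}}.
#' @return list with elements \code{samples} (data.frame),
#'   \code{expression} (probe-level \linkS4class{BrainExpression}),
#'   \code{probeMap} (data.frame), \code{rnaseq} (gene-level
#'   \linkS4class{BrainExpression} for donors 1-2), \code{statVolume}
#'   (\linkS4class{StatVolume}, p_value semantics), \code{truth} (list),
#'   \code{config}.
#' @export
generateDataset <- function(cfg) {
    stopifnot(inherits(cfg, "syntheticConfig"))
    set.seed(cfg$seed)
    vox <- cfg$voxelSizeMm
    margin <- 2 * vox
    axes <- .support_axes(cfg)
    clusters <- cfg$clusters

    ## ---- sample placement -------------------------------------------
    place_compartment <- function(comp, nTotal, drawRegion) {
        cl <- clusters[clusters$compartment == comp, , drop = FALSE]
        nIn <- sum(cl$n_samples)
        if (nIn > nTotal)
            stop("cluster sample counts exceed ", comp, " total")
        inPts <- do.call(rbind, lapply(seq_len(nrow(cl)), function(i)
            .runif_ball(cl$n_samples[i],
                        as.numeric(cl[i, c("x", "y", "z")]),
                        cl$radius_mm[i] - margin)))
        if (is.null(inPts)) inPts <- matrix(numeric(0), ncol = 3)
        outPts <- .draw_avoiding(nTotal - nIn, drawRegion, clusters,
                                 margin)
        list(coords = rbind(inPts, outPts),
             inCluster = rep(c(TRUE, FALSE), c(nIn, nTotal - nIn)))
    }
    sub <- place_compartment("subcortex", cfg$nSubcortical,
        function(k) .runif_ball(k, c(0, 0, 0), 35))
    shellDraw <- function(k) {
        s <- (runif(k, 0.55^3, 0.85^3))^(1 / 3)
        .unit_dirs(k) * (s * matrix(axes, k, 3, byrow = TRUE))
    }
    cor_ <- place_compartment("cortex", cfg$nCortical, shellDraw)
    nBs <- cfg$nExcluded %/% 2L
    nCb <- cfg$nExcluded - nBs
    exc <- rbind(.runif_ball(nBs, c(0, -25, -50), 10),
                 .runif_ball(nCb, c(0, -50, -40), 12))

    coords <- rbind(sub$coords, cor_$coords, exc)
    n <- nrow(coords)
    compartment <- rep(c("subcortex", "cortex", "brainstem", "cerebellum"),
                       c(cfg$nSubcortical, cfg$nCortical, nBs, nCb))
    inCluster <- c(sub$inCluster, cor_$inCluster, rep(FALSE, nBs + nCb))
    acronyms <- list(
        subcortex = c("GPi", "nbM", "DBv", "LHA", "VMH", "AHA"),
        cortex = c("PCLa", "SFG", "MTG", "ITG", "OrG", "CgGf"),
        brainstem = c("PnRF", "RN"), cerebellum = c("CbCx", "DN"))
    acro <- vapply(seq_len(n), function(i) {
        pool <- acronyms[[compartment[i]]]
        pool[1L + (i %% length(pool))]
    }, character(1))
    donors <- paste0("donor", sample.int(cfg$nDonors, n, replace = TRUE))
    samples <- data.frame(
        sample_id = sprintf("S%04d", seq_len(n)),
        donor_id = donors,
        structure_acronym = acro,
        structure_name = paste0(compartment, " structure ", acro),
        compartment = compartment,
        mni_x = coords[, 1], mni_y = coords[, 2], mni_z = coords[, 3],
        stringsAsFactors = FALSE)

    ## ---- gene-level signal ------------------------------------------
    k <- length(cfg$genes)
    baseline <- setNames(seq(4, 9, length.out = k), cfg$genes)
    retained <- compartment %in% c("subcortex", "cortex")
    pAff <- sum(inCluster & retained) / sum(retained)

    ## latent factors for planted in-cluster correlations
    lambda <- setNames(rep(0, k), cfg$genes)
    pairs <- cfg$coexprEffect
    factorTerm <- matrix(0, k, n, dimnames = list(cfg$genes, NULL))
    if (!is.null(pairs) && nrow(pairs)) {
        for (i in seq_len(nrow(pairs))) {
            lam <- cfg$noiseSd * sqrt(pairs$r[i] / (1 - pairs$r[i]))
            f <- rnorm(n)
            for (g in c(pairs$gene_a[i], pairs$gene_b[i])) {
                factorTerm[g, ] <- factorTerm[g, ] +
                    lam * f * inCluster
                lambda[g] <- lambda[g] + lam^2
            }
        }
    }

    ## shift calibrated to land at effectZ on the z-scored scale:
    ## global variance sigma0^2 = noise^2 + pAff * lambda^2, and the
    ## shift itself adds pAff(1-pAff) * shift^2
    shift <- vapply(cfg$genes, function(g) {
        dz <- cfg$effectZ[[g]]
        if (dz == 0) return(0)
        s0sq <- cfg$noiseSd^2 + pAff * lambda[[g]]
        denom <- 1 - dz^2 * pAff * (1 - pAff)
        if (denom <= 0)
            stop("effectZ for ", g, " too large to calibrate")
        dz * sqrt(s0sq / denom)
    }, numeric(1))

    donorOffsets <- matrix(rnorm(k * cfg$nDonors, 0, cfg$donorOffsetSd),
                           k, cfg$nDonors,
                           dimnames = list(cfg$genes,
                                           paste0("donor",
                                                  seq_len(cfg$nDonors))))
    signal <- baseline + outer(shift, as.numeric(inCluster)) +
        factorTerm + matrix(rnorm(k * n, 0, cfg$noiseSd), k, n)
    geneExpr <- signal + donorOffsets[, donors]
    colnames(signal) <- colnames(geneExpr) <- samples$sample_id

    ## ---- probes ------------------------------------------------------
    probeOffsets <- c(1.5, seq(0, -0.5,
                               length.out = max(cfg$probesPerGene - 1L,
                                                1L)))[seq_len(cfg$probesPerGene)]
    probeNoise <- c(0.05, rep(0.5, max(cfg$probesPerGene - 1L, 0L)))
    probeMap <- data.frame(
        probe_id = as.vector(vapply(cfg$genes, function(g)
            sprintf("%s_p%d", g, seq_len(cfg$probesPerGene)),
            character(cfg$probesPerGene))),
        gene_symbol = rep(cfg$genes, each = cfg$probesPerGene),
        stringsAsFactors = FALSE)
    probeExpr <- matrix(0, nrow(probeMap), n,
                        dimnames = list(probeMap$probe_id,
                                        samples$sample_id))
    for (j in seq_len(nrow(probeMap))) {
        g <- probeMap$gene_symbol[j]
        slot_ <- (j - 1L) %% cfg$probesPerGene + 1L
        probeExpr[j, ] <- geneExpr[g, ] + probeOffsets[slot_] +
            rnorm(n, 0, probeNoise[slot_])
    }

    ## ---- RNA-seq companion: donors 1-2 only, strictly monotone in the
    ## per-sample gene abundance (donor differences are tissue-borne, so
    ## they appear on both platforms)
    rnaDonors <- paste0("donor", 1:2)
    rnaCols <- samples$sample_id[donors %in% rnaDonors]
    rnaseq <- 2^(geneExpr[, rnaCols, drop = FALSE] / 2)

    ## ---- statistic volume -------------------------------------------
    d <- cfg$volumeShape
    aff <- .volume_affine(cfg)
    idx <- as.matrix(expand.grid(i = 0:(d[1] - 1), j = 0:(d[2] - 1),
                                 k = 0:(d[3] - 1)))
    world <- idx %*% t(aff[1:3, 1:3]) +
        matrix(aff[1:3, 4], nrow(idx), 3, byrow = TRUE)
    support <- rowSums(sweep(world, 2, axes, `/`)^2) <= 1
    grid <- ifelse(support, 1.0, 0)
    for (i in seq_len(nrow(clusters))) {
        ctr <- as.numeric(clusters[i, c("x", "y", "z")])
        dd <- sqrt(rowSums(sweep(world, 2, ctr)^2))
        grid[dd <= clusters$radius_mm[i]] <- cfg$pFloor
    }
    vol <- StatVolume(grid = array(grid, dim = d), affine = aff,
                      semantics = "p_value")

    truth <- list(
        samples = data.frame(sample_id = samples$sample_id,
                             compartment = compartment,
                             donor_id = donors,
                             in_cluster = inCluster,
                             stringsAsFactors = FALSE),
        genes = data.frame(gene_symbol = cfg$genes,
                           effect_z = unname(cfg$effectZ[cfg$genes]),
                           raw_shift = unname(shift),
                           baseline = unname(baseline),
                           high_intensity_probe =
                               sprintf("%s_p1", cfg$genes),
                           stringsAsFactors = FALSE),
        pairs = if (is.null(pairs)) data.frame() else pairs,
        donorOffsets = donorOffsets,
        femaleDonor = paste0("donor", cfg$nDonors))

    list(samples = samples,
         expression = BrainExpression(probeExpr, "log2_intensity",
                                      sampleInfo = samples),
         probeMap = probeMap,
         rnaseq = BrainExpression(rnaseq, "rnaseq"),
         statVolume = vol, truth = truth, config = cfg)
}

#' Ground-truth report tables
#'
#' @param truth the \code{truth} element of a generated dataset.
#' @return list of data.frames: \code{samples} (per-sample in-cluster
#'   status), \code{genes} (planted per-gene effects), \code{pairs}
#'   (planted co-expression).
#' @export
truthReport <- function(truth) {
    list(samples = truth$samples, genes = truth$genes,
         pairs = truth$pairs)
}

#' Write a synthetic dataset in the pipeline's input formats
#'
#' Emits \code{samples.csv}, \code{expression.csv}, \code{probe_map.csv},
#' \code{rnaseq.csv}, \code{stat_map.nii.gz} and truth tables into a
#' directory, in exactly the formats the readers in this package consume.
#'
#' @param ds dataset from \code{\link{generateDataset}}.
#' @param dir output directory.
#' @return invisibly, the directory.
#' @export
writeDataset <- function(ds, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    writeSamples(ds$samples, file.path(dir, "samples.csv"))
    writeExpression(ds$expression, file.path(dir, "expression.csv"))
    write.table(ds$probeMap, file.path(dir, "probe_map.csv"), sep = ",",
                row.names = FALSE, quote = FALSE)
    writeExpression(ds$rnaseq, file.path(dir, "rnaseq.csv"))
    writeStatVolume(ds$statVolume, file.path(dir, "stat_map.nii.gz"))
    rep_ <- truthReport(ds$truth)
    for (nm in names(rep_))
        write.table(rep_[[nm]], file.path(dir,
                    sprintf("truth_%s.tsv", nm)),
                    sep = "\t", row.names = FALSE, quote = FALSE)
    invisible(dir)
}
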