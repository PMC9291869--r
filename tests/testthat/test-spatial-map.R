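test_that("p-value thresholding treats stored zeros as background", {
    vol <- makeVolume(c(6L, 6L, 6L), fill = 0, semantics = "p_value")
    mk <- thresholdMap(vol, 0.05)
    expect_equal(statSemantics(mk), "binary_mask")
    expect_equal(sum(statGrid(mk)), 0)   # p = 0 stored means no data

    g <- array(1, c(6L, 6L, 6L)); g[2, 3, 4] <- 0.01
    vol2 <- StatVolume(g, statAffine(vol), "p_value")
    mk2 <- thresholdMap(vol2, 0.05)
    expect_equal(sum(statGrid(mk2)), 1)
    expect_equal(statGrid(mk2)[2, 3, 4], 1)

    expect_error(thresholdMap(vol, alpha = 1.5), "alpha")
})

test_that("mask voxel count equals an exhaustive scan of (0, alpha)", {
    set.seed(9)
    g <- array(runif(8000), c(20L, 20L, 20L))
    g[sample(8000, 500)] <- 0
    vol <- StatVolume(g, diag(4), "p_value")
    mk <- thresholdMap(vol, 0.05)
    expect_equal(sum(statGrid(mk)), sum(g > 0 & g < 0.05))
})

test_that("trilinear interpolation is exact at voxel centers and linear between", {
    set.seed(1)
    g <- array(runif(1000), c(10L, 10L, 10L))
    vol <- StatVolume(g, diag(4), "score")
    # voxel centers: world == voxel index under the identity affine
    for (idx in list(c(0, 0, 0), c(3, 7, 2), c(9, 9, 9))) {
        v <- trilinearSample(vol, idx)
        expect_equal(as.numeric(v), g[idx[1] + 1, idx[2] + 1, idx[3] + 1],
                     tolerance = 1e-15)
    }
    # midpoint between voxels valued 0 and 1 -> 0.5
    g2 <- array(0, c(4L, 4L, 4L)); g2[3, , ] <- 1
    vol2 <- StatVolume(g2, diag(4), "score")
    expect_equal(as.numeric(trilinearSample(vol2, c(1.5, 1, 1))), 0.5)

    # unit cube, corner values 0..7 binary-coded by corner index
    g3 <- array(0, c(2L, 2L, 2L))
    for (cx in 0:1) for (cy in 0:1) for (cz in 0:1)
        g3[cx + 1, cy + 1, cz + 1] <- cx + 2 * cy + 4 * cz
    vol3 <- StatVolume(g3, diag(4), "score")
    w <- c(0.25, 0.5, 0.75)
    expected <- 0
    for (cx in 0:1) for (cy in 0:1) for (cz in 0:1)
        expected <- expected + (cx + 2 * cy + 4 * cz) *
            (if (cx) w[1] else 1 - w[1]) *
            (if (cy) w[2] else 1 - w[2]) *
            (if (cz) w[3] else 1 - w[3])
    expect_equal(as.numeric(trilinearSample(vol3, w)), expected,
                 tolerance = 1e-15)

    expect_error(trilinearSample(vol, c(NA, 1, 1)), "finite")
})

test_that("interpolated values stay within the neighboring voxel range", {
    set.seed(2)
    g <- array(runif(512), c(8L, 8L, 8L))
    aff <- diag(c(2.5, 3, 1.25, 1)); aff[1:3, 4] <- c(-5, 2, 7)
    vol <- StatVolume(g, aff, "score")
    pts <- cbind(runif(200, -5, 12), runif(200, 2, 23),
                 runif(200, 7, 15.7))
    vals <- trilinearSample(vol, pts)
    outside <- attr(vals, "outside")
    expect_true(all(vals[!outside] >= min(g) - 1e-12))
    expect_true(all(vals[!outside] <= max(g) + 1e-12))
    # out-of-support points return 0 and are flagged
    far <- trilinearSample(vol, c(1000, 0, 0))
    expect_equal(as.numeric(far), 0)
    expect_true(attr(far, "outside"))
})

test_that("classification excludes hindbrain samples and honors both modes", {
    # 5-voxel-radius suprathreshold sphere centered mid-volume
    d <- c(21L, 21L, 21L)
    g <- array(1, d)
    ctr <- c(10, 10, 10)
    idx <- as.matrix(expand.grid(0:20, 0:20, 0:20))
    g[sqrt(rowSums(sweep(idx, 2, ctr)^2)) <= 5] <- 0.01
    vol <- StatVolume(array(g, d), diag(4), "p_value")
    s <- data.frame(sample_id = c("a", "b", "c"),
                    donor_id = "d1", structure_acronym = "X",
                    structure_name = "",
                    compartment = c("subcortex", "cortex", "cerebellum"),
                    mni_x = c(10, 2, 10), mni_y = c(10, 2, 10),
                    mni_z = c(10, 2, 10))
    clsA <- classifySamples(s, vol, mode = "interpolate_then_threshold")
    clsB <- classifySamples(s, vol, mode = "threshold_then_interpolate")
    for (cls in list(clsA, clsB)) {
        expect_equal(cls$label, c("affected", "unaffected", NA))
        expect_equal(cls$excluded, c(FALSE, FALSE, TRUE))
        expect_equal(cls$excluded_reason[3], "cerebellum")
    }
    # out-of-volume sample is excluded with reason, never unaffected
    s2 <- s; s2$mni_x[2] <- 500
    cls2 <- classifySamples(s2, vol)
    expect_true(cls2$excluded[2])
    expect_equal(cls2$excluded_reason[2], "outside-volume")
})

test_that("classification agrees with the point-in-sphere oracle on generated data", {
    ds <- generateDataset(smallConfig(seed = 21))
    cls <- classifySamples(ds$samples, ds$statVolume)
    cl <- ds$config$clusters
    # geometric oracle: distance to any cluster center under its radius
    inSphere <- rep(FALSE, nrow(ds$samples))
    for (i in seq_len(nrow(cl))) {
        dd <- sqrt((ds$samples$mni_x - cl$x[i])^2 +
                   (ds$samples$mni_y - cl$y[i])^2 +
                   (ds$samples$mni_z - cl$z[i])^2)
        inSphere <- inSphere | dd <= cl$radius_mm[i]
    }
    keep <- !cls$excluded
    expect_equal(cls$label[keep] == "affected", inSphere[keep])
    # partition: affected + unaffected + excluded = total
    expect_equal(sum(cls$label == "affected", na.rm = TRUE) +
                 sum(cls$label == "unaffected", na.rm = TRUE) +
                 sum(cls$excluded), nrow(ds$samples))
    # invariance under sample reordering
    perm <- sample(nrow(ds$samples))
    cls2 <- classifySamples(ds$samples[perm, ], ds$statVolume)
    expect_equal(cls2[order(cls2$sample_id), -1],
                 cls[order(cls$sample_id), -1], ignore_attr = TRUE)
    expect_equal(sort(cls2$sample_id), sort(cls$sample_id))
})

test_that("group counts tabulate compartments and drop excluded samples", {
    expect_equal(sum(countByGroup(makeClassification(character(0),
                                                     character(0)))), 0)
    cls <- rbind(makeClassification(c("a", "b", "c"), "affected",
                                    "subcortex"),
                 makeClassification(c("d", "e"), "unaffected", "cortex"))
    tab <- countByGroup(cls)
    expect_equal(tab["subcortex", "affected"], 3L)
    expect_equal(tab["cortex", "unaffected"], 2L)
    expect_equal(sum(tab), 5L)

    # generator ground truth: planted cluster counts recovered exactly
    ds <- generateDataset(smallConfig(seed = 33))
    tab2 <- countByGroup(classifySamples(ds$samples, ds$statVolume))
    expect_equal(tab2["subcortex", "affected"], 40L)
    expect_equal(tab2["cortex", "affected"], 25L)
    expect_equal(sum(tab2), 270L)
})
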