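test_that("sample tables load with explicit compartments and preserve order", {
    f <- withr::local_tempfile(fileext = ".csv")
    writeLines(c("sample_id,donor_id,structure_acronym,compartment,mni_x,mni_y,mni_z",
                 "s1,d1,GPi,subcortex,1,2,3",
                 "s2,d1,SFG,cortex,-4,5,6",
                 "s3,d2,CbCx,cerebellum,7,-8,9"), f)
    s <- readSamples(f)
    expect_equal(nrow(s), 3L)
    expect_equal(s$sample_id, c("s1", "s2", "s3"))
    expect_equal(s$compartment, c("subcortex", "cortex", "cerebellum"))
    expect_equal(s$mni_x, c(1, -4, 7))
})

test_that("sample loading enforces columns, coordinates and acronym lookup", {
    f <- withr::local_tempfile(fileext = ".csv")
    writeLines(c("sample_id,donor_id,structure_acronym,compartment,mni_x,mni_y,mni_z",
                 "s1,d1,GPi,subcortex,NaN,2,3"), f)
    expect_error(readSamples(f), "mni_x")

    writeLines(c("sample_id,donor_id,mni_x,mni_y,mni_z",
                 "s1,d1,1,2,3"), f)
    expect_error(readSamples(f), "structure_acronym")

    # no compartment column: resolved through the lookup, unknown acronyms
    # are reported by name
    writeLines(c("sample_id,donor_id,structure_acronym,mni_x,mni_y,mni_z",
                 "s1,d1,GPi,1,2,3",
                 "s2,d1,XXX,4,5,6"), f)
    lk <- data.frame(structure_acronym = "GPi", compartment = "subcortex")
    expect_error(readSamples(f, lk), "XXX")
    lk2 <- rbind(lk, data.frame(structure_acronym = "XXX",
                                compartment = "cortex"))
    s <- readSamples(f, lk2)
    expect_equal(s$compartment, c("subcortex", "cortex"))
})

test_that("a generated sample table round-trips through write/read", {
    ds <- generateDataset(smallConfig(seed = 11))
    f <- withr::local_tempfile(fileext = ".csv")
    writeSamples(ds$samples, f)
    back <- readSamples(f)
    expect_equal(nrow(back), nrow(ds$samples))
    expect_equal(back$sample_id, ds$samples$sample_id)
    expect_equal(back$compartment, ds$samples$compartment)
    expect_equal(back[, c("mni_x", "mni_y", "mni_z")],
                 ds$samples[, c("mni_x", "mni_y", "mni_z")],
                 tolerance = 1e-12)
})

test_that("expression tables load, reject duplicates, and round-trip", {
    f <- withr::local_tempfile(fileext = ".csv")
    writeLines(c("id,s1,s2,s3", "p1,1.5,2,3", "p2,4,5,6.25"), f)
    e <- readExpression(f)
    expect_s4_class(e, "BrainExpression")
    expect_equal(dim(e), c(2L, 3L))
    expect_equal(rownames(e), c("p1", "p2"))
    expect_equal(exprValues(e)["p2", "s3"], 6.25)
    expect_equal(valueKind(e), "log2_intensity")

    writeLines(c("id,s1,s2", "p1,1,2", "p1,3,4"), f)
    expect_error(readExpression(f), "duplicate")
    writeLines(c("id,s1,s2", "p1,1,x"), f)
    expect_error(readExpression(f), "missing or non-numeric")

    # write -> read -> write reproduces the file byte-identically
    ds <- generateDataset(smallConfig(seed = 3))
    f1 <- withr::local_tempfile(fileext = ".csv")
    f2 <- withr::local_tempfile(fileext = ".csv")
    writeExpression(ds$expression, f1)
    writeExpression(readExpression(f1), f2)
    expect_identical(readLines(f1), readLines(f2))
})

test_that("statistic volumes read from NIfTI with grid and affine intact", {
    vol <- makeVolume(c(10L, 10L, 10L), fill = 0, semantics = "p_value")
    f <- withr::local_tempfile(fileext = ".nii.gz")
    writeStatVolume(vol, f)
    back <- readStatVolume(f, "p_value")
    expect_equal(statGrid(back), statGrid(vol))
    expect_equal(statAffine(back), statAffine(vol))

    # synthetic map round-trip: voxel values within 1e-6, affine exact
    ds <- generateDataset(smallConfig(seed = 5))
    writeStatVolume(ds$statVolume, f)
    back <- readStatVolume(f, "p_value")
    expect_lt(max(abs(statGrid(back) - statGrid(ds$statVolume))), 1e-6)
    expect_equal(statAffine(back), statAffine(ds$statVolume))
})

test_that("degenerate volumes are rejected", {
    aff <- diag(4); aff[2, ] <- 0    # singular affine
    expect_error(StatVolume(array(0, c(3, 3, 3)), aff, "p_value"),
                 "invertible")
    expect_error(StatVolume(array(0, c(3, 3, 3, 2)), diag(4), "p_value"),
                 "3-D")
    expect_error(StatVolume(array(2, c(3, 3, 3)), diag(4), "p_value"),
                 "0, 1")
    # a 4-D file on disk is rejected by the reader
    f <- withr::local_tempfile(fileext = ".nii.gz")
    RNifti::writeNifti(RNifti::asNifti(array(0, c(4, 4, 4, 2))), f)
    expect_error(readStatVolume(f), "3-D")
})

test_that("result tables are written deterministically with fixed columns", {
    d1 <- withr::local_tempdir()
    writeResults(list(), d1)
    de <- read.delim(file.path(d1, "differential_expression.tsv"))
    expect_equal(nrow(de), 0L)
    expect_true(all(c("gene", "compartment", "p_bonf") %in% names(de)))

    row <- data.frame(map_name = "m", compartment = "subcortex",
                      gene = "OXTR", n_affected = 3L, n_unaffected = 4L,
                      rank_sum_U = 10, mean_diff_z = 0.5, p_raw = 0.01,
                      m_tests = 6L, p_bonf = 0.06, significant = FALSE,
                      untestable = FALSE)
    d2 <- withr::local_tempdir()
    d3 <- withr::local_tempdir()
    writeResults(list(differential = row,
                      summary = list(alpha = 0.05)), d2)
    writeResults(list(differential = row,
                      summary = list(alpha = 0.05)), d3)
    t2 <- readLines(file.path(d2, "differential_expression.tsv"))
    expect_equal(length(t2), 2L)
    expect_identical(t2,
        readLines(file.path(d3, "differential_expression.tsv")))
    expect_identical(readLines(file.path(d2, "summary.json")),
                     readLines(file.path(d3, "summary.json")))
})
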