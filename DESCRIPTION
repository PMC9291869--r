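Package: oxtmap
Title: Imaging Transcriptomics of Oxytocin Pathway Genes in fMRI-Defined
    Brain Regions
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Links microarray expression samples from a donor brain atlas
    to volumetric fMRI statistic maps in MNI-152 space. Samples are
    classified as falling inside or outside suprathreshold ("affected")
    regions by trilinear interpolation of the statistic volume at each
    sample's MNI coordinate, stratified into cortical and subcortical
    compartments. Differential expression between affected and unaffected
    samples is assessed with Wilcoxon rank-sum tests under Bonferroni
    control, and differential co-expression with a Steiger chi-square test
    for equality of correlation matrices followed by pairwise two-sample
    Fisher r-to-z contrasts. Includes probe selection by intensity with
    RNA-seq validation, additive donor batch correction, and a synthetic
    data generator that emulates atlas samples, expression matrices and
    statistic volumes with known ground truth so that the whole pipeline
    is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
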