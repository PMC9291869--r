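---
title: "Mapping oxytocin-pathway expression onto fMRI-defined brain regions: methods and design"
author: "oxtmap authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping oxytocin-pathway expression onto fMRI-defined brain regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oxtmap)
```

## The question and the data

Intranasal oxytocin changes task-evoked brain activity in some fMRI
experiments, but whether it can act directly on central oxytocin
receptors is unresolved. One way to probe this is spatial: if the brain
regions whose activity responds to intranasal oxytocin express more
*OXTR* than regions that do not respond, direct receptor binding becomes
a plausible mechanism. oxtmap implements this imaging-transcriptomics
analysis as a reusable, tested pipeline.

Two data modalities meet in MNI-152 space:

* **Atlas expression samples.** A donor-brain microarray atlas supplies
  a few thousand tissue samples, each with a donor id, an anatomical
  structure label, a compartment (cortex, subcortex, brainstem,
  cerebellum) and an MNI coordinate, plus a probe-level log2-intensity
  matrix and a probe-to-gene annotation. A smaller RNA-seq matrix exists
  for a subset of donors.
* **Statistic volumes.** Meta-analytic *p*-statistic maps of the
  oxytocin-versus-placebo contrast, stored as NIfTI-1 volumes whose
  affine maps voxel indices to MNI mm.

The genes of interest are the oxytocin pathway (*OXT*, *OXTR*, *CD38*)
and the vasopressin receptors (*AVPR1A*, *AVPR1B*, *AVPR2*) as
specificity controls.

## The procedure

1. **Probe selection.** Each gene has several probes; the one with the
   highest mean intensity across all samples represents the gene. "Highest
   expression" is operationalised as the arithmetic row mean (the
   plausible alternatives — median, maximum — are not what intensity
   filtering conventionally means, and the mean is the only choice that
   makes the selection linear in the data); exact ties break toward the
   lexicographically smallest probe id so the choice is deterministic.
   When RNA-seq is available, the selection is validated by checking that
   the chosen probe also attains the highest Spearman correlation with
   the same gene's RNA-seq values over shared samples. A failed
   validation warns and keeps the intensity choice: validation is
   confirmatory, not a second selector.

2. **Classification.** Each statistic volume is thresholded at
   $\alpha = 0.05$. A sample is *affected* when the volume, trilinearly
   interpolated at the sample's MNI coordinate, passes the threshold;
   otherwise *unaffected*. Brainstem and cerebellum samples are excluded
   up front, and samples falling outside the volume's support are
   excluded with an explicit reason rather than silently labeled
   unaffected. Counting affected/unaffected per compartment reproduces
   the audit table that motivates stratifying every later test by
   cortex/subcortex.

3. **Preprocessing.** Expression values are corrected for additive donor
   (batch) effects per gene — the least-squares one-factor model, i.e.
   subtract each donor's mean and restore the grand mean — then
   z-normalized per gene across *all* retained samples jointly.
   Normalizing per compartment would erase the cortex/subcortex contrast
   the analysis reports, so it is deliberately global. Normalization
   happens after sample exclusion (the excluded hindbrain samples never
   contribute to the moments); this ordering is recorded in the run
   manifest. For the male-only analysis the female donor's columns are
   dropped *before* batch correction, so the remaining donors' corrections
   are computed purely within the male subset.

4. **Differential expression.** Per map, per compartment and per gene, a
   two-sided Wilcoxon rank-sum test compares z-scored expression in
   affected versus unaffected samples; the reported effect size is the
   mean z difference (affected − unaffected). The Bonferroni family is
   the set of genes tested within one compartment × map (six genes by
   default); the family size is written into every output row because
   the choice of family is the kind of detail that otherwise disappears.

5. **Differential co-expression.** On the designated map, Pearson
   correlation matrices of the six genes are computed separately in
   affected and unaffected samples of a compartment. Matrix equality is
   tested with the Steiger chi-square
   $\chi^2 = \sum_{i<j} (z^{(1)}_{ij} - z^{(2)}_{ij})^2 / (1/(n_1-3) +
   1/(n_2-3))$ on $k(k-1)/2$ degrees of freedom, where
   $z = \operatorname{atanh}(r)$. Focus-gene pairs (default focus:
   *OXTR*) are then contrasted with the two-sample Fisher r-to-z test,
   Bonferroni-corrected over the retained pairs.

## Decisions where the design was genuinely open

* **Interpolate-then-threshold versus threshold-then-interpolate.** Both
  readings of "falling inside the mask" are implemented. The default
  interpolates the continuous statistic and applies the single
  $\alpha$ criterion, because it needs no second arbitrary cutoff; the
  mask-membership mode (any positive interpolated mask value counts) is
  available via `mode = "threshold_then_interpolate"`. The choice is
  recorded in the manifest, and for points farther than one voxel from a
  cluster boundary the two coincide — the synthetic generator places all
  samples in that regime so tests can pin down both modes at once.
* **Stored zeros in p-value volumes** are treated as background outside
  the analysis mask, not as $p = 0$: statistic maps conventionally
  zero-fill non-brain voxels, and reading them as infinitely significant
  would classify empty space as affected.
* **Pair filtering before the Fisher contrast.** A pair is retained when
  its correlation is Bonferroni-significant in *at least one* group
  (`filterRule = "either"`). The strict "both groups" reading would make
  it impossible to detect a correlation present in only one group —
  exactly the phenomenon of interest (e.g. a receptor pair coupled only
  inside affected regions). The strict rule remains available.
* **Gating the pairwise contrasts on the Steiger test** is implemented
  but off by default; with it on, a non-significant matrix test
  suppresses all pairwise contrasts in that compartment.
* **Compartment assignment** is accepted from an explicit column or a
  caller-supplied acronym lookup; the package does not re-derive the
  anatomical ontology.

## The synthetic data generator

Real atlas and map downloads are large and access-gated, so the
generator builds inputs with the same shapes and known ground truth.
Defaults define the study conditions and are not tuned per test:

* 986 subcortical, 1762 cortical and 150 hindbrain samples across six
  donors (the last tagged female so the male-only path is exercisable) —
  the scale of one atlas crossed with one map.
* Two spherical suprathreshold clusters (radius 16 mm): one subcortical
  holding 180 planted samples, one cortical holding 140; the statistic
  volume stores $p = 0.01$ in cluster voxels, 1.0 elsewhere inside an
  ellipsoidal brain support, 0 outside. In-cluster samples are drawn at
  least 2 voxels (8 mm) inside the sphere and all others at least 8 mm
  outside it, so membership is unambiguous under interpolation and the
  planted counts are exact.
* Expression per gene: baseline + donor offset ($N(0, 1)$ per
  gene × donor) + in-cluster mean shift + in-cluster latent factor +
  $N(0, 1)$ noise. Three probes per gene are the gene signal plus probe
  noise; one designated probe has both the highest offset and the least
  noise, so intensity selection and RNA-seq validation have a known right
  answer. RNA-seq for donors 1–2 is a strictly monotone transform
  ($2^{x/2}$) of the per-sample abundance.
* **Calibrated planting.** A raw mean shift of $\delta$ would not land
  at $\delta$ on the z scale, because global z-normalization divides by a
  standard deviation inflated by the shift itself and by the latent
  factor. The generator solves the closed form
  $\text{shift} = \delta \sqrt{\sigma_0^2 / (1 - \delta^2 p(1-p))}$,
  with $\sigma_0^2$ the no-shift variance and $p$ the affected fraction
  of retained samples, so the planted *OXTR* effect of 1.0 z-units is
  recovered by the full pipeline within ±0.1 on average. The latent
  factor loading $\sigma\sqrt{r/(1-r)}$ plants an in-cluster correlation
  of $r$ (default: *OXTR*–*AVPR1A* at $r = 0.4$), visible after donor
  correction.

What the generator does **not** emulate: spatial autocorrelation of real
expression, anatomical geometry beyond spheres-in-an-ellipsoid,
non-additive donor effects, and probe-specific hybridization artefacts.
Passing tests therefore demonstrate that the machinery is correct and
calibrated under an additive Gaussian model at realistic sizes — not
that real atlas data satisfy that model.

## Numerical conventions and degenerate inputs

* Trilinear interpolation works in 0-based continuous voxel coordinates
  obtained through the full inverse affine (oblique and anisotropic
  grids included); voxel centers reproduce stored values exactly and
  out-of-support points return 0 with an `outside` flag.
* The rank-sum p-value is exact (enumeration distribution) when the
  pooled sample size is ≤ 12 with no ties, otherwise a normal
  approximation with tie-corrected variance and continuity correction.
* z-normalization uses the $n-1$ sample standard deviation;
  zero-variance genes are an error naming the gene, not a silent NaN.
* The Steiger statistic diverges at $|r| = 1$ off-diagonal; this is an
  error, as is any correlation group smaller than 4 samples.
* Empty affected groups mark a compartment's tests `untestable` rather
  than producing fabricated p-values; an empty retained-pair set is a
  valid co-expression outcome.
* All file outputs round numeric values to 8 significant digits and use
  fixed column orders, making reruns byte-identical.

## Problem sizes used in the test suite

The suite regenerates everything in code. Structural tests run on a
reduced atlas (150 subcortical / 120 cortical / 20 excluded samples,
planted clusters of 40 and 25); calibration and power checks use the
full 180-affected/806-unaffected subcortical design over 200 generator
seeds, and 1000 Monte-Carlo draws for the type-I-error band of the
rank-sum stage. These sizes give binomial error bars comfortably inside
the asserted bands while keeping a full run of the suite around three
minutes.

## Known limitations

* Samples pooled across donors are treated as independent observations
  in every $n$; donor correction removes mean shifts but not
  donor-specific covariance.
* Bonferroni control is per compartment × map family; no across-map
  correction is attempted, mirroring the stratified reporting the
  pipeline audits.
* The Steiger and Fisher tests are normal-theory approximations; no
  permutation or spatially-aware null is provided.
* Compartment labels are taken as given; misassigned acronyms propagate.
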