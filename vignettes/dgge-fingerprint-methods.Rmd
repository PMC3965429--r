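---
title: "Methods: DGGE fingerprints, functional PCA, and distance-based inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: DGGE fingerprints, functional PCA, and distance-based inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dggefp)
```

## Scope and data model

`dggefp` analyzes densitometric DGGE lane profiles — intensity as a
function of standardized migration distance (Rf in [0, 1]) — for a
sediment-incubation study design with four crossed factors: sample
fraction (bulk DNA / RNA / whole cell), station (LF1, LF1.5, LF3, LF5),
redox condition (oxic / anoxic) and nutrient amendment (control / CNP),
plus pre-incubation *in situ* samples. In-situ samples are coded as a
third level of **both** redox and amendment; the two levels are therefore
perfectly confounded, and all inference is sequential (Type-I) so the
confounded variation is attributed to whichever term is fitted first.
Coding in-situ as extra levels (rather than dropping those samples) keeps
the pre-incubation baseline in every ordination and dendrogram.

The central container is the fingerprint matrix: samples × 101 bins of
relative intensities, each row summing to 1 (bin 1 = top of the gel). The
choice of 101 equal-width bins over the cropped gel region is a fixed
design constant of the workflow, not a tuning parameter.

## Lane processing

* **Background subtraction**: a moving minimum over a window (default
  0.05 Rf) followed by a moving average of the same width — a
  morphological-opening analogue. Residual negative intensities are
  clamped to zero, because relative intensities must be non-negative for
  normalization and correspondence analysis. The window must only be wide
  relative to band widths (default bands: σ = 0.004 Rf); baselines varying
  on scales ≫ the window are removed almost completely.
* **Alignment**: monotone piecewise-linear warps through matched anchor
  pairs (marker bands), with linear extrapolation outside the anchor span,
  then linear resampling onto the reference pixel grid. Non-monotone
  anchors are an error, never silently reordered.
* **Binning**: trapezoid integration of the profile over each of the 101
  equal sub-intervals of the crop, divided by the lane total. Integrating
  area (not averaging samples) makes the result invariant to resampling
  density and to positive rescaling of a lane's intensities.
* **Masking** (sensitivity re-analysis): a bin range — default 71–74, the
  region of the dominant band — is set to exactly zero in every row
  *without renormalizing*. Renormalizing would change every other bin
  relative to the unmasked analysis; keeping row sums at 1 − masked mass
  makes the masked and unmasked analyses directly comparable. A mask that
  removes all remaining mass from any lane is an error.

## Functional PCA

Each fingerprint row is smoothed by a cubic smoothing spline (penalty
λ∫f″²; `stats::smooth.spline` with all knots). A **single λ shared across
rows** keeps the implicit basis common so scores are comparable; with
`lambda = "gcv"` the shared value is the median of per-row GCV selections.
`lambda = 0` is the exact no-smoothing limit, under which FPCA with
uniform quadrature weights reproduces ordinary PCA of the bin matrix (this
identity is asserted in the tests against `prcomp`).

The smoothed curves are centered by the pointwise mean and the
quadrature-weighted sample covariance is eigendecomposed (trapezoid
weights on the bin-center grid; the scheme reduces to uniform weights up
to edge effects). Harmonics have unit quadrature norm, are mutually
orthogonal, and are sign-flipped so each harmonic's largest-magnitude
value is positive — a pure display convention that provably leaves
variance proportions, distances, and dendrogram heights unchanged (also
asserted). The number of retained harmonics defaults to the smallest K
reaching 90% cumulative variance; on the synthetic study this is typically
15–20 of the 146 computable components. Centering is by the functional
mean only — bins are already on a common relative-intensity scale, so no
per-bin rescaling is applied.

## Distance-based statistics

All downstream statistics operate on Euclidean distances between the FPCA
score vectors.

* **Ward clustering** uses the `ward.D2` Lance–Williams convention
  (squared distances), the correct Ward objective for Euclidean input;
  the historical `ward.D` variant is available behind a flag because early
  R defaults differed. Merge heights equal `sqrt(2 ΔESS)` and are verified
  against a naive implementation that recomputes within-cluster variance
  directly.
* **Ordination**: the default reproduces the study workflow literally —
  correspondence analysis applied to the entries of the distance matrix.
  Chi-square machinery on distances is statistically unorthodox (distances
  are not counts), so classical principal-coordinates analysis is provided
  behind `ordinate(D, "pcoa")`. Whether the original procedure was
  intentional or shorthand for PCoA cannot be decided from its description;
  both routes are first-class and tested.
* **Vector fitting**: each bin's abundance is regressed on the first two
  ordination axes; r² is the regression R², the arrow is the unit
  coefficient vector, and p-values permute the variable's values with the
  observed statistic included: p = (1 + #{r²* ≥ r²}) / (1 + n_perm).
  Constant variables are flagged (r² = 0, p = 1), not errors.
* **PERMANOVA**: Gower-centered squared distances G = −½ J D² J;
  sequential SS via trace differences of cumulative hat matrices;
  pseudo-F with residual df; p by free permutation of sample rows (no
  strata — the study pools fractions and stations in a single analysis).
  Degrees of freedom are rank increments of the cumulative dummy design,
  computed by SVD with singular values below 1e-8 × the largest counted as
  zero. Dummy matrices are integer-valued, so aliasing is exact and this
  tolerance is uncritical. On the reconstructed 147-sample inventory the
  sequential Df column is fully design-determined: fraction 2, station 3,
  redox 2, amendment 1 (aliased in-situ level), …, residuals 91.

An explicit `permutations` matrix can replace random draws in both
`permanova()` and `fit_vectors()`; the tests use this to compare against
exhaustive enumeration exactly rather than approximately.

Both `group_anova()` (one-way ANOVA, via `aov`) and `students_t()`
(pooled-variance two-sample t) handle their degenerate inputs explicitly:
all-identical values give F = 0 (t = 0, p = 1), and zero within-group
variance with distinct means is flagged as exact separation (infinite
statistic) rather than NaN.

## Tag propagation

A sequenced band's taxon tag is given to all lanes' bins at the same gel
height. Conflicts are resolved per bin:

* all tags agree → one global label;
* tags consistent within each tagged station but differing across
  stations → per-station labels, untagged stations `"unknown"`;
* two or more different tags *within* one station → a double label `A/B`
  (alphabetical), built from the two most frequent tag names in the bin
  (ties alphabetical);
* no tags → `"unknown"`.

The source description of the double-tag rule also mentions the case of a
station with no tag while "other stations" carry more than one different
tag; read literally that clause overlaps the per-station rule, so this
package interprets it as referring to conflicts within a single other
station — per-station labeling applies whenever every tagged station is
internally consistent. This is the only reading consistent with the
workflow's own example of a tag that "differed across stations". The same
ambiguity appears in the original workflow's handling of its dominant
band (three Cyanobacteria tags and one Proteobacteria tag from four
lanes resolved to a single Cyanobacteria label); the rules as stated
would emit a double or per-station label there, so no special case is
added — the discrepancy is documented rather than guessed at.

`"unknown"` is an ordinary tag value: bands sequenced but classified below
the confidence threshold arrive already labeled `"unknown"`, and
propagation/conflict rules treat them like any other label. Class-level
labels roll up to phylum level through a user-supplied two-column mapping;
unmapped classes become `"unknown"`. Group abundances conserve lane mass
by construction (the `unknown` group absorbs unlabeled mass), a property
asserted on randomized inputs including masked matrices.

## The synthetic gel generator

The generator defines the study conditions under which everything is
tested:

* **Design**: the full inventory — 48 incubations (4 × 2 × 2 × 3), bulk
  DNA and RNA samples for every incubation plus in-situ samples (2 and 1
  per station respectively), and 39 whole-cell samples spread round-robin
  so every treatment cell keeps at least one (which of the 48 incubations
  lack whole-cell samples is not recorded in the study description; the
  round-robin fill is this package's deterministic choice).
* **Communities**: 30 taxa, band positions uniform on (0.05, 0.95), band
  σ = 0.004 Rf, log-scale abundance noise σ = 0.3, closed to compositions.
  Treatment effects are additive on the log scale per (factor level,
  taxon).
* **Dominant band**: a taxon at the center of bin 72 is re-closed to 35%
  of the composition in the in-situ bulk-DNA lanes of the two shallow
  stations, to 30% of that in their incubated bulk-DNA lanes and 15% of it
  in their in-situ RNA lanes, and left at background in whole-cell lanes —
  mirroring the reported depth profile of settled cyanobacterial plankton
  DNA (abundant as extracellular DNA, scarce as intact or active cells).
* **Warps**: per-lane monotone piecewise-linear warps with anchor jitter
  σ = 0.01 Rf (roughly one bin); additive truncated-Gaussian pixel noise.

What the generator deliberately does **not** emulate: gel-image artifacts
(lane smiling, saturation, bleed), heteroduplex bands, PCR amplification
bias, and within-band sequence heterogeneity. Passing tests therefore
demonstrate correctness of the numerical pipeline under an idealized
densitometric model, not robustness to image-level pathologies.

## Statistical verification and problem sizes

The test suite verifies, among others: type-I error of the PERMANOVA
permutation test at α = 0.05 over 1000 null synthetic datasets (24
samples, 999 permutations each; the rejection count must fall inside the
exact binomial 99% interval); monotone increase of mean redox R² in the
planted effect size over δ ∈ {0, 0.5, 1, 2} with 20 seeds each and ≥90%
rejection at δ = 2; and recovery of planted group abundances within 1% on
truth-tagged gels. The scaled 24-sample design (one station, one fraction,
2 × 2 × 6) keeps these Monte-Carlo studies fast while preserving the
two-factor structure; the full 147-sample design is exercised end-to-end
for the design arithmetic, degrees of freedom, and the pipeline runs.

## Known limitations

* Correspondence analysis of a distance matrix (the default ordination)
  has no chi-square sampling interpretation; use `"pcoa"` for orthodox
  geometry.
* The per-row GCV → median-λ rule can select effectively zero smoothing
  for spiky compositional profiles; that is the honest GCV answer for
  near-noiseless synthetic lanes, and a fixed λ can be supplied where
  smoothing is wanted for its own sake.
* Free permutation is the only PERMANOVA scheme; restricted/blocked
  permutations are out of scope.
* Alignment assumes the warp is piecewise-linear between marker anchors;
  warps curving between anchors leave residual mis-registration of up to
  a few pixels.
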