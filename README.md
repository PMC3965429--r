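# dggefp

Community-fingerprint analysis for denaturing gradient gel electrophoresis
(DGGE), built around functional PCA of lane intensity profiles and
distance-based multivariate statistics on unbalanced factorial designs.

## The problem

DGGE separates same-length 16S rRNA gene amplicons by melting behavior, so
each gel lane is a densitometric fingerprint of one sample's bacterial
community: intensity as a function of standardized migration distance (Rf).
Comparing dozens of lanes across treatments raises a chain of statistical
questions that this package answers as one tested pipeline:

1. **Lane processing** — background subtraction, monotone piecewise-linear
   alignment to marker bands, cropping, and integration into a 101-bin
   relative-intensity fingerprint per lane (rows are compositional: they
   sum to 1).
2. **Functional PCA** — each fingerprint is smoothed with a cubic smoothing
   spline and the quadrature-weighted covariance of the curves is
   eigendecomposed. The eigenfunctions ("harmonics") ξ_k and per-sample
   scores s_ik = ∫ (x_i(t) − μ(t)) ξ_k(t) dt summarize whole-profile
   variation, keeping band positions related instead of treating bins as
   independent variables.
3. **Distance-based statistics** — Euclidean distances on the FPCA scores
   feed Ward (`ward.D2`) clustering, ordination (correspondence analysis of
   the distance matrix, with classical PCoA as an alternative), least-squares
   vector fitting of individual bins into the ordination plane with
   permutation r², and a sequential (Type-I) PERMANOVA:
   with G = −½ J D² J (Gower-centered squared distances),
   SS_term = tr(H_cum G) − tr(H_prev G), pseudo-F = (SS/df)/(SS_res/df_res),
   and p-values by free permutation of sample rows. Degrees of freedom are
   rank increments of the cumulative dummy design, so perfectly confounded
   factor levels (pre-incubation "in situ" samples coded on both redox and
   amendment) and empty design cells are attributed to the first term that
   spans them.
4. **Taxon tags** — phylogenetic tags from sequenced, excised bands are
   propagated to all lanes at the same gel height with station-wise
   conflict-resolution rules, then summed into phylum/class abundance
   tables and compared across treatments by one-way ANOVA.
5. **Synthetic gels** — a generator with known taxa, planted log-scale
   treatment effects, lane-to-lane monotone warping, and a dominant
   "settled plankton" band near bin 72 makes every stage testable without
   real gel images. Its default design is 147 samples: 48 incubations
   (4 stations × 2 redox × 2 amendments × 3 replicates) sampled as bulk
   DNA, RNA and whole-cell fractions plus in-situ samples (56 + 52 + 39).

## Worked example

```r
library(dggefp)
cfg <- run_config(seed = 42, n_perm = 199, envfit_n_perm = 199)
res <- run_pipeline(cfg, "runs/demo")

res$original$fpca
#> <fpca_model: 147 samples, 17 harmonics (90.9% of variance), lambda = 1.22e-15>

head(as.data.frame(res$original$permanova)[, c("term","Df","F","R2","p","stars")], 4)
#>        term Df     F      R2     p stars
#> 1  fraction  2 18.94 0.11373 0.005    **
#> 2   station  3  9.33 0.08406 0.005    **
#> 3     redox  2 15.27 0.09170 0.005    **
#> 4 amendment  1  1.11 0.00335 0.275
```

The run simulates the full 147-lane synthetic study, renders and processes
the lanes into 101-bin fingerprints, and fits FPCA (17 harmonics cover 90%
of curve variance here). The PERMANOVA table attributes distance-based
variance sequentially: the `Df` column is design-determined (amendment has
1 df because its in-situ level is aliased with the redox in-situ level
fitted before it; residuals have 91 df), while F, R² and p reflect the
planted community structure. Vector-fitting the bins into the ordination
plane identifies the planted dominant band:

```r
env <- as.data.frame(res$original$envfit)
env$variable[which.max(env$r2)]   #> "bin_072"  (r2 = 0.75)
```

Because a mask is configured (bins 71–74, the dominant-band region), the
pipeline also writes a masked re-analysis; excluding the band drops the
apparent redox signal sharply (redox R² 0.092 → 0.019 in this run), showing
how a single dominant band of extracellular DNA can masquerade as a
treatment effect.

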