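---
title: "From sparse Psi50 measurements to community embolism-resistance maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From sparse Psi50 measurements to community embolism-resistance maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hydromap)
```

`hydromap` chains four analyses: phylogenetic signal in xylem embolism
resistance (Ψ50), taxonomic group comparisons, taxonomic gap-filling into
community-weighted means (CWM), and spatial generalisation with explicit
uncertainty diagnostics. This vignette explains the models behind each
stage, the tunable parameters and their defaults, the numerical choices,
and what the synthetic-data generator does and does not emulate.

## The trait and its sign conventions

Ψ50 is the xylem water potential at which hydraulic conductivity has
dropped to half its maximum, in MPa. It is negative by definition, and
*more negative means more embolism-resistant*. All tables in the package
store Ψ50 on this native scale; input validation rejects non-negative
values. Because the distribution of |Ψ50| is right-skewed, normalising
transformations operate on the absolute value: `sqrt` and `cbrt` map
|Ψ50| so that *larger transformed values mean more resistant xylem*.
`choose_transformation()` codifies the usual screening workflow: try
`none`, `sqrt`, `cbrt` in that order and keep the first whose
Shapiro-Wilk p reaches 0.05 (else the best of the three). The decision
trace is returned so the choice can be audited.

## Phylogenetic signal

`blomberg_k()` implements the variance-ratio statistic

$$K = \frac{MSE_0/MSE}{E_{BM}[MSE_0/MSE]}, \qquad
\hat a = (1'V^{-1}1)^{-1}1'V^{-1}x,$$

where $V$ is the matrix of shared root-to-MRCA branch lengths
(`tree_covariance()`), $MSE_0$ the mean squared deviation about the
phylogenetic GLS mean $\hat a$, $MSE$ its GLS analogue, and the
denominator the Brownian-motion expectation
$[\mathrm{tr}(V) - n/(1'V^{-1}1)]/(n-1)$. $K \approx 1$ under Brownian
evolution; $K \to 0$ for a trait shuffled across the tree. Two
conventions worth making explicit:

* $MSE_0$ is computed about $\hat a$, not the arithmetic mean — the
  convention of the statistic's standard implementations, so values are
  comparable with the literature.
* K is invariant to affine maps of the trait and to uniform rescaling of
  branch lengths (both are tested properties), so the choice of
  transformation affects K only through non-linearity, not units.

Significance (`permutation_test()`) randomises the assignment of values
to tips, recomputing K each time; the observed K is significant when it
falls outside the central 95% of the null (two-sided percentile rule),
and the reported p carries the +1/+1 correction so it can never be
exactly zero. We permute and recompute the full statistic rather than any
intermediate quantity. Polytomies are accepted; tips without trait data
(or values without tips) are dropped with a message, and fewer than 20
matched tips triggers a warning since K loses power below that size.

`ancestral_states()` returns the maximum-likelihood (joint-Gaussian
conditional-expectation) Brownian reconstruction for every internal node;
the root reconstruction equals $\hat a$ exactly, which the test suite
asserts at 1e-10. `node_randomisation()` compares each node's observed
reconstruction to the distribution of reconstructions under tip
randomisation. The reconstruction is a fixed linear operator applied to
the tip vector, so the operator is precomputed once and each of the 1000
permutations costs a single matrix product. The default tail is `upper`
("more resistant than chance" on the transformed scale) because that is
the scientifically interesting direction for drought resistance; `lower`
and `two_sided` are available. Comparisons against the null use a
relative tolerance of 1e-8 so that a degenerate (constant) trait flags
nothing instead of leaking floating-point ties.

## Taxonomic comparisons

`select_nested_subset()` keeps genera with more than one species or a
species sampled at more than one site, and families with at least two
genera or a genus sampled at more than one site — the minimum replication
for a family/genus/species nested ANOVA. `nested_anova()` uses
sequential (Type-I) sums of squares with every term tested against the
residual mean square, the convention of standard ANOVA software; nested
factors are encoded explicitly (one column per group) so the design
matrix stays small. `family_anova_tukey()` filters families by site
occupancy (default ≥ 3 sites), fits a one-way ANOVA and Tukey's HSD, and
derives a compact letter display by insert-and-absorb, verified in the
tests against a direct quadrature of the studentized-range distribution.

`wilcoxon_rank_sum()` reports W as the rank sum of the first group minus
its minimum (0 ≤ W ≤ n₁n₂, midranks for ties), with an exact enumeration
p when both groups have < 50 values and no ties, and the normal
approximation with tie-corrected variance and 0.5 continuity correction
otherwise. `fabaceae_contrast()` applies it to one family against all
others, optionally within a forest type (dry-season-length class), and
reports group means ± SD on the MPa scale.

## Gap-filling and community-weighted means

`gap_fill()` walks each inventory stem down the ladder species mean →
genus mean → family mean → plot mean, recording the provenance level.
Genus and family means default to means over species-site records (the
granularity of the trait table); a mean-of-species-means switch is
provided since the aggregation convention is a genuine free choice. The
plot-mean fallback is basal-area-weighted by default (consistent with the
CWM it feeds), switchable to unweighted. Name matching is exact after
case/whitespace normalisation — no fuzzy synonymy; unmatched taxa
resolve via coarser levels or the plot mean.

`coverage_filter()` implements the mapping inclusion rule: a plot enters
the spatial analysis only if at least 60% of its *dicot* basal area
belongs to families with trait data. Monocots (palms) are excluded from
the denominator but keep their stems in the CWM when they carry trait
data. `gapfill_validation()` quantifies what family-level imputation
costs: for plots resolvable at species level it regresses the
family-mean-filled CWM on the species-level CWM. On synthetic bundles
with Brownian traits this R² is high (≈ 0.8–0.95) and it degrades
markedly when traits carry no phylogenetic signal — which is exactly the
justification the gap-filling needs, and the package tests assert that
contrast.

## Spatial generalisation

All geometry is planar, in km; projecting longitude/latitude to an
equal-area plane is a documented pre-processing step outside the
algorithms. The feature space for clustering defaults to the plot CWM
plus environmental covariates (MCWD-like and WTD-like), standardised to
zero mean and unit variance.

**Constrained clustering.** `constrained_ward()` agglomerates with the
criterion $(1-\alpha)\delta_0 + \alpha\delta_1$, where $\delta$ are Ward
pseudo-inertia increments computed from the feature-space (D0) and
geographic (D1) dissimilarity matrices under uniform weights,
$I(C) = \sum_{i<j\in C} d^2_{ij}/|C|$. Increments follow the
Lance-Williams recurrence (linear, so the mixed criterion updates
exactly); the test suite checks the whole hierarchy against an
exhaustive recomputation from the definition for n ≤ 8 and against plain
Ward clustering at α = 0. D0 and D1 are each rescaled by their maximum
before mixing so α is comparable across unit systems (switchable).
`select_alpha()` turns the usual "inspect the explained-inertia curves"
step into a rule: take the largest α whose feature-space explained
inertia Q0 has dropped at most `q0_tolerance` (default 0.1) below the
α = 0 baseline. The full curves are always returned so a human can
override. The cluster count is deliberately *not* chosen automatically:
`cluster_diagnostics()` emits Q0/Q1 and mean silhouette per k and leaves
the judgement (few clusters, limited spatial overlap) to the analyst.

**Interpolation.** `idw_predict()` is inverse-distance weighting over the
`nmax` nearest points with weights $d^{-idp}$; a query within 1e-9 map
units of a data point returns that point's value exactly, avoiding the
singularity. `loocv_search()` tunes `idp` and `nmax` by leave-one-out
RMSE with a coarse-to-fine search: each step evaluates the grid, then the
idp grid is re-centred on the incumbent with its span shrunk threefold
(three steps by default). Ties break toward smaller idp, then smaller
nmax, making the search fully deterministic.
`fold_averaged_surface()` interpolates one surface per cross-validation
fold from the *other* folds' points, smooths each with a truncated 9×9
mean filter (edge windows shrink rather than inventing values outside the
domain), and averages cell-wise; a use-all-points mode exists for a
single-surface variant. Averaging across fold surfaces damps the
leverage of any single spatial cluster of plots.

**Validation.** `spatial_cv()` uses the spatial clusters as folds —
a deliberately hard test, since held-out clusters must be predicted from
far-away points — and reports per-fold and pooled RMSE plus
$VEcv = (1 - SSE/SST) \times 100$ over all held-out predictions. It also
compares each cluster's point-average CWM with the mean of interpolated
cells inside the cluster's convex hull, the coarse agreement check that
the interpolation is a visualisation of regional tendency, not a
pixel-accurate data layer. `mess()` implements the rank-based
environmental similarity score: per variable, with $f$ the percentage of
reference values strictly below the query,
$S = 100(p-\min)/(\max-\min)$ if $f=0$; $2f$ if $0<f\le50$; $2(100-f)$
if $50<f<100$; $100(\max-p)/(\max-\min)$ if $f=100$; the cell score is
the worst variable's score and negative values flag extrapolation. Note
a folk description of this score — "50 means all variables are at the
centre of their ranges" — does not follow from the formula (the centre
of the *rank* distribution scores 100); we implement the canonical
formula and note the discrepancy here. Zero-range reference variables
score 100 on an exact match and a large negative sentinel (-1e9, with a
warning) otherwise. The strictly-below convention makes a query at the
reference minimum score exactly 0.

## The synthetic-data generator

The generator's defaults encode the study conditions the package
targets: 88 genus tips, an 11-site trait campaign with three
dry-season-length classes, 448 plots on a 3000 × 2000 km domain, a 60%
coverage threshold, 1000 permutations, a 9×9 smoothing window, 50 km
synthetic rasters. Values the conditions do not fix were chosen once on
field realism: 400 stems per plot (≈ 1-ha stem density at ≥ 10 cm dbh),
log-normal basal areas (right-skewed stem sizes), species- and
record-level noise of 0.3/0.25 MPa, `bm_sigma2 = 0.8` (tip SD near
1 MPa), and a logistic west–east gradient of strength 6 in the resistant
family's stem probability.

* `simulate_yule_tree()` builds a pure-birth tree by explicit lineage
  splitting, stopping one exponential waiting time after the split that
  creates the n-th lineage, so all pendant edges are positive and the
  root-to-tip depth has the closed-form mean $(H_n - 1)/\lambda$ used as
  a test oracle.
* `simulate_bm_traits()` evolves Brownian motion along edges and mixes
  tip deviations with i.i.d. noise of matched marginal variance:
  `signal_lambda` = 1 is pure Brownian motion (K ≈ 1 in expectation),
  0 is pure noise (K ≪ 1, permutation test non-significant). The
  variance matching makes the knob interpretable as a signal fraction
  spanning the empirically interesting K range (≈ 0.4) between the
  anchors.
* `simulate_trait_table()` derives families and orders as clades cut at
  fixed fractions of tree depth, so taxonomy and phylogeny agree by
  construction.
* `simulate_inventories()` plants the compositional gradient and leaves
  deliberate gaps: ~35% of stems carry unmeasured species epithets
  (genus-level fill), ~5% unknown genera (family-level fill), ~3% palms
  without trait data (plot-mean fill and coverage-denominator
  exclusion).
* `simulate_env_rasters()` smooths white noise into autocorrelated
  fields rescaled to MCWD-like (≈ -600–0 mm) and WTD-like (≈ 0–40 m)
  ranges, with a weak deterministic west–east trend in the MCWD field.

What the generator does *not* emulate: real species pools or floristic
nestedness, realistic climate fields (the rasters are generic Gaussian
fields), measurement error structure of pneumatic vulnerability curves,
taxonomic synonymy problems, or multi-census plot dynamics. Passing
tests therefore demonstrate the correctness and statistical calibration
of the chain under its stated assumptions — not that any particular real
landscape satisfies those assumptions.

## Numerical choices and degenerate inputs

* Constant traits raise a degenerate-data error in `blomberg_k()`
  (MSE₀ = 0 has no meaningful ratio); a singular tree covariance raises
  an ill-conditioned-tree error.
* All permutation machinery takes explicit integer seeds; a bundle seed
  derives stage seeds deterministically, and the pipeline manifest
  records them, so every number in every output table is reproducible.
* IDW ties in the LOOCV search and neighbour selection are broken
  deterministically (smaller idp, smaller nmax; stable distance
  ordering).
* The mean filter uses a summed-area table, so smoothing is exact
  arithmetic, not FFT approximation, and edge windows truncate.
* Problem sizes in the test suite (e.g. 200 trees of 100 tips for the
  Brownian calibration, 50-seed pipeline-recovery loops at 120 plots,
  oracle checks at n ≤ 10) are the package's chosen desk-scale study
  sizes: large enough for the Monte-Carlo tolerances asserted, small
  enough to run routinely.

## Known limitations

* No Pagel's λ or Ornstein-Uhlenbeck signal models; K plus
  randomisation is the implemented repertoire.
* No taxonomic name resolution; matching is exact after normalisation.
* No kriging or variogram modelling — IDW is used as a visualisation of
  regional tendency, and the spatial-CV results (deliberately) show how
  much fine-grained structure it misses.
* The pipeline's map products should be read as regional patterns with
  the reported RMSE/VEcv and MESS caveats, never as pixel-level trait
  predictions.
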