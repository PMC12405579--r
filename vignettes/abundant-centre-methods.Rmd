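---
title: "Methods: testing the abundant-centre hypothesis with abundicentre"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: testing the abundant-centre hypothesis with abundicentre}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abundicentre)
```

## The question and its operationalisation

The abundant-centre hypothesis holds that a species is most abundant
near the centre of its geographic range and rarer towards the edges. It
rests on strong assumptions — that the range reflects the niche, that
environmental suitability declines smoothly and monotonically from the
centre outwards, and that populations are near demographic equilibrium —
so empirical support must be measured, not presumed.

The package operationalises the hypothesis in geographic space, per
species, as the sign of the Spearman rank correlation $r_s$ between
$\log_{10}$(abundance) and $\log_{10}$(distance to the range centroid).
Spearman's statistic is used because abundance–suitability relationships
are at best monotone, not linear, and because it is invariant to the
(arbitrary) monotone scalings of abundance measures across source
studies; the $\log_{10}$ transforms therefore change nothing in $r_s$
itself but match how the variables are handled and plotted throughout.
$r_s < 0$ is scored as an abundant-centre pattern, $r_s \ge 0$
(including exactly 0) as the inverse abundant-edge pattern.

## Per-species statistics

**Cleaning.** Records with nonpositive or missing abundance or distance
are removed and logged; species with fewer than five remaining
observations are excluded (the boundary, exactly five, is retained).
Zero distances and zero abundances are removed rather than offset,
because Spearman correlations are unaffected by monotone transforms and
an offset could only change which records survive cleaning.

**Correlation and p-value.** $r_s$ is the Pearson correlation of
mid-ranks (average ranks under ties). For tie-free samples with
$n \le 8$ the two-sided p-value comes from the exact permutation null
distribution of $r_s$ (enumerated once per $n$ and cached); for larger
or tied samples it uses the standard t approximation
$t = r_s\sqrt{(n-2)/(1-r_s^2)}$ on $n-2$ df. The exact small-sample
branch follows the convention of `stats::cor.test`; at these sample
sizes the t approximation alone can err by ~0.05 in p, which matters
when species with $n$ near the cutoff are scored as significant.
$|r_s| = 1$ yields the smallest representable positive p and is flagged.

**Effect sizes and weights.** Correlations become Fisher's
$Z = \operatorname{atanh}(r_s)$, approximately normal with variance
depending only on $n$. $|r_s| = 1$ is clamped at $1 - 10^{-12}$ before
the transform (capping $|Z|$ near 14) so downstream weighted models stay
finite; clamps are flagged. Each species carries the meta-analytic
weight $w_i = \ln n_i$, down-weighting sparsely sampled species without
letting the enormous spread of sampling effort (5 to thousands of
observations) dominate.

## Range geometry

Ranges are lon/lat polygons (expert maps where available, otherwise
minimum convex polygons of the occurrence points — the standard proxy
for under-surveyed taxa). Distances are great circles by the haversine
formula on the WGS84 *mean* sphere, $R = 6371.0088$ km. The phrase
"geodesic distances on a sphere under WGS84" is internally ambiguous
(WGS84 is an ellipsoid); the spherical great circle is used because the
analysis operates on ranks of distances, where the sub-0.5% spherical
vs. ellipsoidal discrepancy is immaterial.

The range centroid is the planar shoelace area centroid of the outer
ring minus holes, computed in a longitude frame recentered on the
polygon's longitudinal midpoint so ranges straddling the antimeridian
are handled, and mapped back to $[-180, 180]$. This matches the default
behaviour of desktop GIS centroid tools on geographic coordinates and
is deliberately *not* a spherical centre of mass; polygons enclosing a
pole are rejected because no recentered planar frame represents them.
Range areas (km²) are spherical polygon areas on the same radius, holes
subtracted, and absolute latitude is $|$centroid latitude$|$. Multi-part
ranges are summarised part-wise (area-weighted centroid, summed area) —
the only consistent extension when sources split ranges.

Study-scale annotations follow fixed bins: extent (the larger
bounding-box axis span, in great-circle km) classed Local/Landscape/
Regional/Continental with contiguous lower-inclusive boundaries at
250/500/1500 km (the source convention leaves (250, 251] undefined;
contiguous intervals are the only consistent reading), and grain/focus
areas binned small/large at $10^{-3}$ km² on the $\log_{10}$ scale with
the boundary in the lower bin. These are annotations only; they are
never auto-included in model formulas, since at compilation scale they
collapse into (and collide with) the taxonomic grouping variables.

## Weighted meta-analytic models

All species-level models are weighted least squares on Fisher's $Z$ with
weights $w_i$, maximum-likelihood error variance
$\hat\sigma^2 = \mathrm{RSS}_w/n$, and Gaussian log-likelihood including
the $\tfrac12\sum\ln w_i$ constant, so AIC values
($-2\ell + 2k$, $k$ counting coefficients plus the variance) are
comparable across models of the same data. Categorical predictors use
treatment coding with the alphabetically first level as reference
(deterministic across runs); continuous predictors can be standardised
to unit (weighted) variance so effects are per-SD comparable.

* **Grand mean**: intercept-only model; "significant" means the t-based
  95% CI excludes zero.
* **Stepwise selection**: backward only, from the full model; at each
  step every droppable term gets a nested-model F-test (categorical
  terms dropped as whole blocks), the largest p above 0.05 is removed,
  and ties are broken by term name order. Terms never re-enter; a term
  with p exactly 0.05 is kept.
* **All-subsets dredge**: every combination of main effects and two-way
  interactions obeying marginality (an interaction only alongside both
  main effects), each fitted by the same weighted ML machinery and
  ranked by AIC. With $m$ candidate main effects this enumerates
  $\sum_k \binom{m}{k} 2^{\binom{k}{2}}$ models — 1450 at $m=5$ and
  40069 at $m=6$, matching the candidate-model counts reported for
  compilations of this design, which is a useful external check on the
  enumeration scheme. The best set is every model with $\Delta$AIC < 2
  ($\Delta$AIC = 0 ties all stay); the final interaction model is the
  union of terms across the best set, with aliased terms pruned
  (interactions first) if that union is collinear. Enumeration refuses
  above a configurable cap (default $10^5$).
* **Marginal effects**: counterfactual averages — the predictor of
  interest is set to each level (or a 10-point grid over its observed
  range) in every observed row, the design matrix is rebuilt and
  averaged with the model weights. Continuous covariates thus sit at
  weighted means and other categorical predictors at observed-frequency
  weights; CIs are delta-method t-intervals. The reference-grid
  convention is documented and tested for internal consistency (the
  frequency-weighted average of level predictions reproduces the fitted
  weighted mean); no external convention is asserted.
* **Collinearity screen**: pairwise Pearson $|r| \ge 0.70$ among
  continuous predictors flags pairs that should not share a model.

## Phylogenetic signal

The Brownian covariance $C$ of a rooted tree has $C_{ij}$ equal to the
shared root-to-MRCA branch length. Pagel's $\lambda \in [0, 1]$ scales
its off-diagonal: 0 erases phylogenetic structure, 1 leaves full
Brownian covariance. $C$ is converted to a correlation matrix before the
$\lambda$ transform, making $\lambda$ comparable across non-ultrametric
trees; observation weights, when used, enter as
$V = D^{1/2}\,\mathrm{corr}(C(\lambda))\,D^{1/2}$ with $D =
\mathrm{diag}(1/w_i)$. Whether published analyses of this design carry
their meta-analytic weights inside the GLS is generally unstated; here
weights are on by default for model fits and off for residual tests
(residuals are already on the weighted model's scale), and both
configurations are runnable.

$\hat\lambda$ maximises the multivariate normal likelihood with mean and
variance profiled analytically; the scalar search on $[0,1]$ uses
Brent's method (tolerance $10^{-6}$) with both endpoints evaluated
explicitly, so the reported optimum never undercuts $\lambda = 0$ or 1.
The likelihood-ratio test against $\lambda = 0$ uses $\chi^2_1$ without
a boundary correction, matching the field's common tooling; values of
$\lambda > 1$ are not explored. Zero-length branches are padded to
$10^{-8}$ and a $10^{-10}$ diagonal jitter is the fallback when a
Cholesky factorisation fails. PGLS fits at $\lambda \in
\{0, 1, \hat\lambda\}$ are compared by AIC ($k$ counts coefficients,
the variance, and $\lambda$ when fitted); at $\lambda = 0$ the fit
reduces exactly to (weighted) least squares, which the tests pin to
$10^{-8}$. Species missing from the tree are dropped with a warning —
compiled phylogenies rarely cover every species in an abundance
compilation.

## The synthetic-data generator

Because compiled multi-study abundance data cannot be bundled, the
generator produces data with the statistical structure the analysis
assumes, with known truth:

* **Species-level effects.** Each species' true mean
  $Z_i = \operatorname{atanh}(\rho_s) + \text{trait shifts} + u_i$,
  where $u$ is drawn under $\lambda$-Brownian motion on a simulated Yule
  tree. Trait effects are additive on mean $Z$ — exactly the structure
  the linear meta-model estimates. Defaults, chosen once as the
  emulated study conditions: baseline $\rho_s = -0.1$ (a weak
  abundant-centre tendency), a +0.15 shift for the tree-like functional
  group and −0.04 per unit $\log_{10}$ height, $\lambda_{\rm true} =
  0.2$ (the magnitude at which fitted-λ corrections become consequential
  in compilations of this kind), $\sigma^2_{BM} = 0.04$ (between-species
  $Z$ spread ≈ 0.2), and functional-group frequencies 65/386/29/120 per
  600 (grass/herb/shrub/tree).
* **Observations.** In copula mode, abundance–distance pairs come from
  a Gaussian copula with latent Pearson correlation
  $2\sin(\pi\rho_s/6)$ — exact for the bivariate normal latent scale —
  so the *population* Spearman correlation equals the species' target
  $\tanh Z_i$; margins are strictly positive lognormals (zero-abundance
  handling is exercised by corrupt fixtures instead, not by the
  generator). Distances are rank-preservingly rescaled into the range
  radius and realised as sites at random bearings, so re-deriving
  distances from the range centroid reproduces the target correlation.
  In spatial mode, sites are uniform on the spherical cap and abundance
  is $\exp(\alpha - g\,d/r + \varepsilon)$ — an explicit centre-peaked
  ($g>0$), flat or edge-peaked field. Per-species sampling effort is
  log-uniform on [5, 2000]: the compilation this emulates spans 5 to
  tens of thousands with means of 1–3 thousand, and the upper tail is
  cut because it adds cost but no statistical structure that matters at
  package scale.
* **Trees.** Pure-birth (Yule) trees rescaled to unit root-to-tip
  depth, making $\lambda$ and $\sigma^2$ identifiable and comparable
  across sizes.

What the generator does **not** emulate: real range shapes, spatial
autocorrelation of the environment, density dependence, observation
error models specific to survey protocols, or non-equilibrium range
dynamics. Passing tests therefore demonstrate that the estimators
recover the assumed structure, not that the assumptions hold in any
real assemblage.

## Numerical and design choices

* Percentages in group summaries are rounded half-away-from-zero to one
  decimal for parity with published tables.
* The exact-permutation Spearman null is enumerated only to $n = 8$
  (40320 permutations, cached); beyond that the t approximation is
  accurate and tie-tolerant.
* The seed fixes every generator output byte-for-byte; the pipeline is
  a pure function of (inputs, config, seed), and reruns produce
  byte-identical CSV/JSON artefacts.
* Degenerate geometry (collinear hulls, zero-area polygons,
  pole-crossing rings) and undefined correlations (constant vectors)
  raise typed errors rather than propagating NaN.
* Candidate dredge models whose design is rank-deficient (e.g. a rare
  binary trait crossed with a covariate) are skipped with a warning —
  the alternative, silently dropping aliased columns, would make AIC
  values incomparable.

## Problem sizes

The bundled tests and the acceptance script run at deliberately modest
scale, chosen as the sizes at which every statistical property they
check is already stable: simulated assemblages of 8–80 species with
5–2000 observations each, λ recovery on 200–300-tip trees, null and
power simulations of 15–100 replicates. All are the package's own
choices and can be raised freely via `simulation_config()`.

## Known limitations

* Centrality only: distance-to-edge (marginality) statistics and
  ecological-niche-space distances are out of scope.
* The λ model assumes Brownian motion; other signal statistics
  (Blomberg's K, Moran's I) and OU-type models are not implemented, and
  metric choice is known to affect conclusions.
* The planar centroid convention differs from a true spherical centre
  of mass for very large or high-latitude ranges; both conventions
  cannot be right for every range, and the choice is documented rather
  than hidden.
* No publication-bias diagnostics, mixed-effects meta-analysis, or
  spatial-autocorrelation corrections; these belong to a different
  modelling layer than the one implemented here.
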