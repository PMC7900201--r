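---
title: "Methods: meso-scale fruit-fall geostatistics and ensemble interpolation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: meso-scale fruit-fall geostatistics and ensemble interpolation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fruitfall)
```

## The problem

Fruit reaching the forest floor ("fruit-fall") transfers biomass and
nutrients from the canopy to the ground fauna and soil, but it is rarely
quantified at the meso scale (tens of square kilometres). The workflow
implemented here targets a masting survey design: 30 sample points on a
~1-km lattice inside a 25 km² grid, three ~500 m² plots per point
(≈ 4.42 ha sampled in total), fruit counts by species converted to dry
biomass with per-species mean fruit masses, and a single dominant masting
species (*Vouacapoua americana*, a Critically Endangered Amazonian timber
tree) whose presence and biomass are analysed against ten remotely sensed
covariates on a 250-m raster.

The package chains five stages:

1. **Responses** — inclusion rules, count→biomass conversion, richness,
   Shannon diversity, dominance ranking.
2. **Spatial structure** — empirical variograms, weighted-least-squares
   nugget/sill/range fits, permutation envelopes for complete spatial
   randomness (CSR).
3. **Explanation** — five a-priori penalized-spline additive models per
   response and backward stepwise selection of a minimal model.
4. **Prediction** — six-member ensemble interpolation (IDW, universal
   kriging, GLM, GAM, random forest, support vector machine) weighted by
   observed–predicted correlation.
5. **Up-scaling** — landscape biomass totals and fractions of
   above-ground biomass (AGB).

A seeded synthetic-landscape generator stands in for the field data, so
every stage is testable end to end.

## Survey responses

Eligible fruit counts include *fresh* and *partially-eaten* fruits;
*rotten*, *dried* and *germinating* fruits are excluded. Species whose
fruits are collected after counting ("removable") sum across repeat
visits; for persistent species the monthly maximum is taken so a fruit
lying on the ground at two visits is counted once. Richness and Shannon
diversity are computed from counts pooled across the survey months.

Dry biomass for a plot is

$$B \;=\; \frac{\sum_s n_s\, m_s / 1000}{A / 10^4 \cdot T}
\quad \left[\mathrm{kg\,ha^{-1}\,month^{-1}}\right],$$

with $n_s$ the eligible count of species $s$, $m_s$ its mean fruit dry
mass (g), $A$ the plot area (m²) and $T$ the survey length in months.
Species without a dry-mass measurement raise an error rather than being
silently imputed. Two scales are carried side by side: monthly rates (for
Table-1-style summaries) and the survey-period total (the default model
response; with a two-month window its SD is twice the monthly SD, which
is the scale on which the RMSE of the fitted models is reported). A
`log1p` column is provided for users who prefer a log-scale gaussian fit;
the default models the untransformed total. The Shannon index uses
natural logarithms, consistent with the 0–1.9 range typical of few-species
plots.

## Spatial structure

The empirical semivariogram is the method-of-moments estimator
$\hat\gamma(h) = \frac{1}{2N(h)}\sum_{(i,j)\in h}(z_i-z_j)^2$ with 15
equal-width lag bins up to half the maximum pairwise distance (common
variogram practice; both are options). Presence is analysed as the
indicator transform $\mathbf{1}[z>0]$ of the biomass response.

Spherical and exponential models are fitted by pair-count-weighted least
squares (weights $N(h)$, all parameters constrained nonnegative,
L-BFGS-B from multiple starts); by default both families are fitted and
the lower weighted SSE kept. For the exponential family the `range`
parameter is the distance constant; its practical range (95% of the
sill) is about three times that. The nugget/sill ratio summarises how
much variance is spatially unstructured.

CSR envelopes permute the observed values across the fixed locations
(999 permutations by default) and take pointwise 2.5–97.5% quantiles per
lag; a min–max band is available via `quantiles = c(0, 1)`. A pointwise
95% band covers the observed semivariance of exchangeable values at
~95% of lags *on average* — it is not a simultaneous band, so single-lag
excursions are expected at roughly 1 lag in 20 and a global test should
not be read off it.

## The a-priori model suite

Five hypotheses are fitted per response with `mgcv`: *Space only*
(2-d thin-plate smooth of the projected coordinates + basin),
*Topography* (altitude, slope, aspect), *Hydrography* (distance to
drainage and topographic wetness smooths, SAGA wetness linear),
*Vegetation cover* (AGLB and three EVI layers) and *Full*. Smooths are
penalized cubic regression splines with basis dimension k = 9 (k = 29
for the spatial smooth — roughly a third of n = 90, and capped
automatically where a covariate has few unique values at the clustered
plots); smoothing parameters are selected by maximum likelihood
(`method = "ML"`), which keeps likelihoods comparable across fixed-effect
structures for AIC/BIC ranking. Biomass uses a gaussian family on the
untransformed response; presence is binomial-logit. Deviance explained
is $100(\mathrm{D}_0-\mathrm{D})/\mathrm{D}_0$, which for the gaussian
family equals $100\,R^2$.

Within each model the numeric covariates are screened for collinearity:
pairs with $|r| \ge 0.7$ (a standard cutoff; the threshold is an option)
lose the member with the weaker absolute correlation to the response,
visited in decreasing $|r|$ so the rule is deterministic.

Backward selection starts from the screened full model and repeatedly
removes the term with the largest approximate p-value ≥ 0.05, provided
the refitted AIC does not rise by more than 2; ties are broken by the
larger AIC improvement, then alphabetically. An empty (intercept-only)
outcome is valid and flagged. Because the *Full* model nests the spatial
smooth, raw AIC comparisons between *Full* and *Space only* mostly
reflect the penalty on near-zero extra smooths; the discriminating
comparison for "is the pattern spatial?" is *Space only* against the
three environmental hypothesis models.

## Ensemble interpolation

Six members predict each response at the plots and over the 250-m grid:

* **IDW** — inverse-distance weighting, power 2, all 90 plots in the
  neighbourhood (the sample is small enough that truncation would only
  discard information).
* **UK** — kriging with a first-order coordinate trend (ordinary kriging
  available via `drift = "constant"`); the variogram is fitted to the
  OLS trend residuals, and each prediction solves the standard
  semivariance system with unbiasedness constraints. Nugget-free UK and
  IDW reproduce training values exactly.
* **GLM / GAM** — linear-term and additive models on the minimal-model
  covariates plus coordinates.
* **RF / SV** — seeded random forest and radial-kernel support vector
  machine on covariates plus coordinates; presence via probability
  outputs.

Member weights are $w_m = \max(0, r_m)/\sum_k \max(0, r_k)$ with $r_m$
the Pearson correlation between observations and the member's in-sample
predictions, following the weighted-mean ensemble definition; negative
correlations are clamped to zero weight so no member can flip the sign
of the surface. In-sample correlation rewards exact interpolators (IDW
and UK get $r = 1$ by construction); a k-fold cross-validated weighting
(`weight_scheme = "cv"`) is available for users who prefer
generalisation-based weights, but the in-sample scheme is the default.
The ensemble surface is the per-pixel weighted mean, hence a convex
combination bounded by the member envelope. Presence pixels with
probability ≥ 0.5 count as occupied; biomass totals are
$\sum_\text{pixels} B \cdot a_\text{px}/1000 \times \text{months}$, with
the number of months the total represents carried explicitly rather than
assumed.

## Up-scaling accounting

The accounting chain annualizes the plot-mean monthly rate (×12 — an
explicit upper bound, since masting is episodic; the result is stored as
`annual_max`), converts rates to landscape totals (rate × area / 1000),
bounds the landscape AGB between the mapped-raster sum and an
extrapolated per-hectare mean, expresses fruit-fall as a percentage of
AGB, and derives per-tree fruit mass (fruits per tree × mean fruit dry
mass) and the implied density of fruiting trees. Every step is linear in
its biomass argument and retains unrounded intermediates; printed
reports round to the conventional 1 dp for rates, integer Mg for large
totals and 2 dp for sub-percent fractions.

## The synthetic landscape

The generator emulates the survey's statistical structure on a
20 × 20 grid of 250-m cells (2500 ha):

* **Covariates.** Altitude is a Gaussian random field (broad component,
  range parameter 400 m, plus 45% finer roughness) rescaled to mean
  117.2, SD 14.5 m. Slope, aspect, the two wetness indices and distance
  to drainage are derived deterministically from it (finite-difference
  gradients; channels at the lowest 12% of cells; wetness increasing
  with flatness and channel proximity). AGLB and the EVI layers are
  independent smooth fields, with `EVI_diff = EVI_dry − EVI_wet` by
  construction (that sign convention matches the published seasonal
  means, 0.60 − 0.49 ≈ 0.11). Every layer is clamped inside the
  published study-area range, and the published SAGA-wetness row is read
  as 7.549 (4.647–11.029), treating its printed thousands separators as
  decimal points. Basins are a three-region Voronoi partition.
* **Fruit-fall.** A hurdle model: Bernoulli occurrence with
  logit-scale intercept 0.93 and a latent Gaussian field
  (partial sill 0.8, range parameter 70 m ≈ 210 m practical — spatial
  dependence confined to a few hundred metres, with a high nugget, as in
  the survey), and a conditional log-normal biomass rate centred on
  41.4 kg ha⁻¹ month⁻¹ (the positive-part mean implied by an overall
  mean of 28.5 across 90 plots with 62 occupied) with plot-level
  dispersion σ = 0.61. Counts are Poisson draws of rate × area ×
  months / fruit mass. A 40-species background pool (log-normal fruit
  masses around 5 g, geometric abundances, ~1.5 species per plot at
  ~136 fruits per occurrence) supplies the other ~57% of counts and
  ~36% of biomass. These constants were set once from the published
  summary arithmetic; with them the generator reproduces presence in
  ~62 of 90 plots, overall biomass ≈ 42–45 kg ha⁻¹ month⁻¹ with SD of
  similar magnitude, dominant-species shares ≈ 43% of counts and
  ≈ 64–68% of biomass, and richness ≈ 45 species ha⁻¹.
* **Design.** Trail plots are exactly 500 m² (2 × 250 m); permanent-plot
  areas are 472.1 m² plus centred jitter, so the 90-plot mean is exactly
  490.7 m² and the total 4.4163 ha. A 5 × 6 lattice (1000 m × 920 m
  spacing) hosts the 30 points: exactly 30 points at exactly 1 km do not
  fit a 5-km extent, so the row spacing is compressed by 8%.
  Contour-following permanent plots are represented by their centroid
  and area only — the analysis consumes nothing else.

What the generator does *not* emulate: real topography-conditioned
hydrology (channels are an altitude threshold, not a flow model),
phenological timing, observation error in species identification, and
any true covariate–fruit-fall coupling (the default couples fruit-fall
to space alone; covariate effects are available as config fields but
default to zero, because the functional link nature uses is unknown).
Passing tests on this landscape therefore demonstrate correctness of the
estimators and plumbing under a realistic spatial hurdle structure — not
ecological validity of any covariate relationship.

## Numerical choices and test problem sizes

Gaussian fields are simulated by exact Cholesky factorisation (the grids
used are a few hundred cells, where exactness is cheaper than spectral
approximations; a 10⁻⁸ relative diagonal jitter guards definiteness).
Kriging systems are solved densely with one factorisation per training
set and all prediction points as right-hand sides; a singular system is
retried once with a diagonal jitter, then errors. Variogram fits
restart L-BFGS-B from 18 grid-spread initialisations. All randomness
flows from a single integer seed (stage offsets +1, +2, +3 keep the
stages independently reproducible), and identical configurations produce
bit-identical rasters, tables and artifacts.

The test suite sizes its simulations for a desk-scale machine: 40
replicate landscapes for the calibration check, 50 fields of 150 points
for range recovery, 50 replicates for the selection and model-ranking
checks, and 100 replicates × 999 permutations for envelope calibration;
the full pipeline itself runs in seconds.

## Known limitations

* Variograms are isotropic; no REML/ML variogram estimation.
* No spatially correlated error structures in the additive models, so
  p-values at clustered plots are somewhat optimistic — one reason the
  stepwise rule also requires AIC non-degradation.
* Kriging variance is not propagated through the ensemble; the ensemble
  spread is not an uncertainty estimate.
* The ×12 annualization is an upper bound, and the implied
  fruiting-tree density divides event totals by a per-tree constant
  measured on two trees — both are order-of-magnitude accounting, not
  demography.
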