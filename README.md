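# fruitfall

Meso-scale geostatistics for forest fruit-fall surveys: plot responses,
variograms with permutation null envelopes, a-priori additive-model
comparison, six-member ensemble spatial interpolation, and landscape
biomass up-scaling.

## What it is for

Tropical-forest fruit-fall — fruit reaching the ground rather than being
eaten in the canopy — moves biomass and nutrients between forest strata,
yet is rarely quantified beyond single stands. This package implements a
complete analysis pipeline for masting surveys of the kind run on
25 km² ecological-research grids: 30 sample points on a ~1-km lattice,
three ~500 m² plots per point (≈ 4.42 ha sampled), per-species fruit
counts converted to dry biomass with reference fruit masses, and a
focal masting species analysed against ten remotely sensed covariates
(altitude, slope, aspect, two wetness indices, distance to drainage,
above-ground live biomass, three EVI layers) on a 250-m raster. It is
aimed at spatial ecologists who want the whole chain — from raw tallies
to "how many megagrams of fruit fell across the landscape, and what
fraction of standing biomass is that?" — reproducible and testable.

Because survey data of this kind are rarely deposited, the package
includes a seeded synthetic-landscape generator
(`simulate_landscape()`) that reproduces the statistical structure of
such a survey (zero-inflated, heavy-tailed biomass with short-range
spatial dependence; one dominant species at ~43% of counts and ~64% of
biomass; ~62 of 90 plots occupied), so the full pipeline runs and is
tested without any downloads.

## The methods

* **Responses.** Eligible counts (fresh + partially-eaten fruit only;
  removable species summed across visits, persistent species not
  double-counted) are converted as
  `B = Σ n_s m_s / 1000 / (A/10⁴) / T` (kg ha⁻¹ month⁻¹), with richness
  per hectare and Shannon `H = −Σ p log p` alongside.
* **Spatial structure.** Method-of-moments semivariogram
  `γ(h) = Σ (z_i − z_j)² / 2N(h)`; spherical/exponential models fitted
  by N(h)-weighted least squares (nugget, partial sill, range); CSR
  envelopes from 999 value permutations across the fixed locations
  (pointwise 2.5–97.5% bands).
* **Explanation.** Five a-priori `mgcv` models per response (Space
  only / Topography / Hydrography / Vegetation cover / Full; penalized
  cubic regression splines, smoothing by maximum likelihood), compared
  on deviance explained, AIC, BIC, RMSE and observed–fitted correlation,
  with within-model collinearity screening (|r| ≥ 0.7) and backward
  stepwise selection (drop p ≥ 0.05 terms unless AIC degrades) of a
  minimal model.
* **Prediction.** Six members — IDW, universal kriging (first-order
  trend), GLM, GAM, random forest, SVM — combined as a weighted mean
  with weights `w_m ∝ max(0, cor(obs, pred_m))`; occupied area and
  landscape totals summarised from the ensemble surfaces.
* **Up-scaling.** `annual_max = monthly × 12`,
  `total Mg = rate × area_ha / 1000`, fractions of above-ground-biomass
  bounds, per-tree fruit mass and implied fruiting-tree density.

See `vignettes/fruitfall-methods.Rmd` for assumptions, defaults and
limitations.

## Worked example

```r
library(fruitfall)

land <- simulate_landscape(sim_config(seed = 42))
responses <- build_response_table(
  land$observations, land$design$plots, land$species_mass, land$stack,
  focal_species = "Vouacapoua americana", n_survey_months = 2)

# spatial structure of the focal species' biomass
xy  <- cbind(responses$Longitude, responses$Latitude)
env <- csr_envelope(xy, responses$biomass, n_perm = 999, seed = 42)
print(env)
#> csr_envelope: 999 permutations, 2.5-97.5% band, observed inside at 14/14 lags

# a-priori model comparison
cmp <- compare_models(apriori_model_specs("biomass", "gaussian"), responses)
print(cmp$table, digits = 3)
#>              model n_vars de_pct  aic  bic rmse   cor
#> 1       Space only      3   7.40 1029 1044 68.8 0.272
#> 2      Hydrography      2   5.15 1030 1044 69.7 0.235
#> 3 Vegetation cover      3   2.30 1032 1044 70.7 0.152
#> 4       Topography      3   1.47 1033 1045 71.0 0.121
#> 5             Full     10  19.06 1035 1072 64.4 0.438

# six-member ensemble interpolation over the 250-m grid
en_b <- ensemble_interpolate(responses, land$stack, "biomass",  seed = 42)
en_p <- ensemble_interpolate(responses, land$stack, "presence", seed = 42)
print(en_b)
#> ensemble_result [biomass]: 6 members
#>   IDW    UK   GLM   GAM    RF    SV
#> 0.230 0.230 0.091 0.102 0.201 0.145
#>   ensemble in-sample cor: 0.976

s <- summarize_prediction_grid(en_p$grid, en_b$grid, land$stack$grid,
                               n_months = 2)
str(s)
#> List of 3
#>  $ occupied_fraction_pct: num 79.2
#>  $ occupied_km2         : num 19.8
#>  $ total_biomass_Mg     : num 251

# up-scaling account (survey constants; masting total from the ensemble)
acct <- upscaling_account(
  mean_monthly = 44.84, area_ha = 2500, masting_total_Mg = s$total_biomass_Mg,
  agb_min_Mg = 694005, agb_max_Mg = 1059500, fruits_per_tree = 4000,
  fruit_mass_g = 18.2, seed_mass_g = 16.2,
  max_plot_monthly = max(responses$biomass_monthly))
print(acct)
#> annual max: 538.1 kg ha^-1 yr^-1 -> 1345 Mg yr^-1 (0.19% of min AGB)
#> masting event: 250.6 Mg = 0.02-0.04% of AGB bounds
#> per tree: 72.8 kg dry fruit (seed fraction 0.89)
```

Reading the output: on this simulated landscape the focal species'
biomass variogram stays inside the complete-spatial-randomness band at
every lag (spatial dependence is confined below the first lag, as the
generator intends); the spatial model ranks first among the four
hypothesis models; the ensemble predicts fruit presence across ~79% of
the grid and a ~251 Mg masting total; and a plot-mean rate of
44.84 kg ha⁻¹ month⁻¹ annualizes to at most 538.1 kg ha⁻¹ yr⁻¹, i.e.
1345 Mg across 2500 ha, ~0.19% of the minimum above-ground-biomass
bound. One full run (`run_pipeline()`) takes a few seconds and writes
every artifact (CSV responses, variogram tables, model comparisons,
ensemble rasters as ESRI ASCII grids, JSON summaries) to its output
directory.

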