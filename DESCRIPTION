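Package: fruitfall
Title: Meso-Scale Fruit-Fall Geostatistics and Ensemble Interpolation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing meso-scale patterns of fallen-fruit dry
    biomass in tropical forest survey grids. Converts plot-level fruit
    counts to dry biomass and diversity responses, quantifies spatial
    structure with empirical variograms, weighted-least-squares variogram
    model fits and complete-spatial-randomness permutation envelopes,
    compares a-priori penalized-spline additive models with backward
    stepwise minimal-model selection, interpolates presence and biomass
    over a 250-m raster grid with a six-member correlation-weighted
    ensemble (inverse distance weighting, universal kriging, GLM, GAM,
    random forest, support vector machine), and up-scales plot rates to
    landscape biomass totals and fractions of above-ground biomass. A
    seeded synthetic-landscape generator reproduces the statistical
    structure of a 30-point, 90-plot masting survey so the full pipeline
    runs without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    mgcv,
    randomForest,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
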