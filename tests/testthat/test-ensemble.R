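test_that("IDW is an exact interpolator and a convex average elsewhere", {
  set.seed(1)
  xy <- cbind(runif(30, 0, 1000), runif(30, 0, 1000))
  z <- rnorm(30, 10, 3)
  at_train <- idw_interpolate(xy, z, xy)
  expect_equal(at_train, z)
  pred <- idw_interpolate(xy, z, cbind(runif(50, 0, 1000),
                                       runif(50, 0, 1000)))
  expect_true(all(pred >= min(z) - 1e-12 & pred <= max(z) + 1e-12))
})

test_that("universal kriging is exact at training points (nugget-free)", {
  set.seed(2)
  xy <- cbind(runif(25, 0, 1000), runif(25, 0, 1000))
  z <- 5 + 0.01 * xy[, 1] + sim_gaussian_field(xy, 1, 300)
  vgm <- structure(list(family = "exponential", nugget = 0, psill = 1,
                        range = 300, sill = 1), class = "variogram_model")
  uk <- uk_interpolate(xy, z, xy, vgm = vgm)
  expect_lt(max(abs(uk$pred - z)), 1e-8)
})

test_that("kriging a constant field returns the constant everywhere", {
  set.seed(3)
  xy <- cbind(runif(20, 0, 500), runif(20, 0, 500))
  vgm <- structure(list(family = "spherical", nugget = 0.5, psill = 1,
                        range = 200, sill = 1.5),
                   class = "variogram_model")
  pred <- uk_interpolate(xy, rep(7, 20),
                         cbind(runif(40, 0, 500), runif(40, 0, 500)),
                         vgm = vgm)$pred
  expect_equal(pred, rep(7, 40), tolerance = 1e-8)
})

test_that("kriging matches a hand-assembled linear system on 3 points", {
  # ordinary kriging, three points, stated exponential variogram; the
  # oracle builds and solves the 4x4 system explicitly
  xy <- rbind(c(0, 0), c(100, 0), c(0, 100))
  z <- c(1, 3, 2)
  x0 <- c(40, 30)
  nug <- 0.2; ps <- 1.5; rg <- 150
  gfun <- function(h) ifelse(h > 0, nug + ps * (1 - exp(-h / rg)), 0)
  D <- as.matrix(dist(xy))
  A <- rbind(cbind(gfun(D), 1), c(1, 1, 1, 0))
  b <- c(gfun(sqrt(colSums((t(xy) - x0)^2))), 1)
  lambda <- solve(A, b)[1:3]
  oracle <- sum(lambda * z)
  vgm <- structure(list(family = "exponential", nugget = nug, psill = ps,
                        range = rg, sill = nug + ps),
                   class = "variogram_model")
  got <- uk_interpolate(xy, z, matrix(x0, 1), vgm = vgm,
                        drift = "constant")$pred
  expect_equal(got, oracle, tolerance = 1e-10)
})

test_that("ensemble weights clamp negatives and normalise", {
  fake <- function(method, ins) structure(
    list(method = method, insample = ins, grid = ins),
    class = "member_prediction")
  obs <- c(1, 2, 3, 4, 5)
  # correlations 0.8 / 0.4 by construction -> weights 2/3, 1/3
  set.seed(9)
  mk <- function(target_r) {
    repeat {
      v <- target_r * scale(obs)[, 1] +
        sqrt(1 - target_r^2) * scale(rnorm(5))[, 1]
      if (abs(cor(obs, v) - target_r) < 0.2) return(v)
    }
  }
  m1 <- fake("IDW", obs)                 # r = 1
  m2 <- fake("UK", -obs)                 # r = -1 -> clamped to 0
  w <- ensemble_weights(list(m1, m2), obs)
  expect_equal(unname(w), c(1, 0))
  expect_equal(sum(w), 1)
  # exact correlations via linear transforms: r is scale-invariant
  m3 <- fake("GLM", 2 * obs + 1)         # r = 1
  w2 <- ensemble_weights(list(m1, m3), obs)
  expect_equal(unname(w2), c(0.5, 0.5))
  # six equal members -> six weights of 1/6
  w6 <- ensemble_weights(rep(list(m1), 6), obs)
  expect_equal(unname(w6), rep(1 / 6, 6))
  # all non-positive correlations: no valid ensemble
  expect_error(ensemble_weights(list(m2), obs), "no valid ensemble")
})

test_that("ensemble combination is the weighted per-pixel mean", {
  fake <- function(g) structure(list(method = "IDW", insample = 1,
                                     grid = g),
                                class = "member_prediction")
  m1 <- fake(rep(10, 6)); m2 <- fake(rep(20, 6))
  expect_equal(ensemble_combine(list(m1, m2), c(0.5, 0.5)), rep(15, 6))
  expect_equal(ensemble_combine(list(m1), 1), rep(10, 6))
  # random grids and weights: elementwise oracle + convexity bound
  set.seed(4)
  gs <- lapply(1:4, function(i) fake(runif(25)))
  w <- runif(4); w <- w / sum(w)
  got <- ensemble_combine(gs, w)
  oracle <- rowSums(mapply(function(m, wi) m$grid * wi, gs, w))
  expect_equal(got, oracle)
  lo <- do.call(pmin, lapply(gs, `[[`, "grid"))
  hi <- do.call(pmax, lapply(gs, `[[`, "grid"))
  expect_true(all(got >= lo - 1e-12 & got <= hi + 1e-12))
  expect_error(ensemble_combine(list(m1, fake(rep(1, 5))), c(0.5, 0.5)),
               "mismatch")
})

test_that("all six members fit, predict on the grid, and respect bounds", {
  land <- default_landscape()
  r <- default_responses()
  np <- land$stack$grid$n_rows * land$stack$grid$n_cols
  for (method in c("IDW", "UK", "GLM", "GAM", "RF", "SV")) {
    mb <- fit_predict_member(method, r, land$stack, "biomass",
                             covariates = c("Altitude", "DND"), seed = 1)
    expect_length(mb$grid, np)
    expect_true(all(is.finite(mb$grid)), info = method)
    expect_true(all(mb$grid >= 0), info = method)
    mp <- fit_predict_member(method, r, land$stack, "presence",
                             covariates = c("Altitude", "DND"), seed = 1)
    expect_true(all(mp$grid >= 0 & mp$grid <= 1), info = method)
  }
  expect_error(fit_predict_member("KNN", r, land$stack, "biomass"),
               "unknown method")
  expect_error(fit_predict_member("IDW", r[1:5, ], land$stack, "biomass"),
               "at least 10")
})

test_that("seeded members and ensembles are reproducible", {
  land <- default_landscape()
  r <- default_responses()
  a <- fit_predict_member("RF", r, land$stack, "biomass", seed = 5)
  b <- fit_predict_member("RF", r, land$stack, "biomass", seed = 5)
  expect_identical(a$grid, b$grid)
  e1 <- ensemble_interpolate(r, land$stack, "biomass",
                             members = c("IDW", "RF"), seed = 5)
  e2 <- ensemble_interpolate(r, land$stack, "biomass",
                             members = c("IDW", "RF"), seed = 5)
  expect_identical(e1$grid, e2$grid)
  expect_identical(e1$weights, e2$weights)
})

test_that("cross-validated weighting is a valid alternative scheme", {
  land <- default_landscape()
  r <- default_responses()
  e <- ensemble_interpolate(r, land$stack, "biomass",
                            members = c("IDW", "GLM"), seed = 3,
                            weight_scheme = "cv", folds = 5)
  expect_equal(sum(e$weights), 1)
  expect_true(all(e$weights >= 0))
  # CV weights no longer reward IDW for its exact in-sample fit
  e_ins <- ensemble_interpolate(r, land$stack, "biomass",
                                members = c("IDW", "GLM"), seed = 3)
  expect_false(identical(e$weights, e_ins$weights))
})

test_that("the ensemble does not degrade far below its best member", {
  cors <- vapply(1:8, function(s) {
    land <- simulate_landscape(sim_config(seed = 8000 + s))
    r <- build_response_table(land$observations, land$design$plots,
                              land$species_mass, land$stack,
                              land$config$dominant_species, 2)
    en <- ensemble_interpolate(r, land$stack, "biomass", seed = s)
    best <- max(vapply(en$members, function(m) cor(r$biomass, m$insample),
                       0))
    cor(r$biomass, en$insample) - best
  }, 0)
  expect_true(all(cors >= -0.05))
})

test_that("grid summaries follow the occupancy and mass arithmetic", {
  g <- grid_spec()   # 400 pixels, 6.25 ha each
  np <- 400
  s <- summarize_prediction_grid(rep(1, np), rep(40, np), g,
                                 n_months = 1)
  expect_equal(s$occupied_fraction_pct, 100)
  expect_equal(s$occupied_km2, 25)
  expect_equal(s$total_biomass_Mg, 100)  # 40 kg/ha x 2500 ha / 1000
  s2 <- summarize_prediction_grid(c(rep(0.8, 100), rep(0.2, 300)),
                                  rep(0, np), g)
  expect_equal(s2$occupied_fraction_pct, 25)
  expect_equal(s2$occupied_km2, 6.25)
  s3 <- summarize_prediction_grid(rep(1, np), rep(40, np), g,
                                  n_months = 2)
  expect_equal(s3$total_biomass_Mg, 200)
})
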