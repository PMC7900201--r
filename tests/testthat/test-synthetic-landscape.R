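test_that("generator is deterministic given the config seed", {
  a <- simulate_landscape(sim_config(seed = 11))
  b <- simulate_landscape(sim_config(seed = 11))
  expect_identical(a$stack$layers, b$stack$layers)
  expect_identical(a$surfaces$presence_prob, b$surfaces$presence_prob)
  expect_identical(a$observations, b$observations)
  c <- simulate_landscape(sim_config(seed = 12))
  expect_false(identical(a$observations, c$observations))
})

test_that("covariate stack has the expected layers inside study ranges", {
  land <- default_landscape()
  st <- land$stack
  expect_length(st$layers, 10)
  expect_setequal(names(st$layers),
                  c("Altitude", "Slope", "Aspect", "TWI", "SWI", "DND",
                    "AGLB", "EVI_wet", "EVI_dry", "EVI_diff"))
  expect_identical(st$layers$EVI_diff,
                   st$layers$EVI_dry - st$layers$EVI_wet)
  ranges <- list(Altitude = c(67, 182), Slope = c(1.3, 19.1),
                 Aspect = c(21.1, 347.1), TWI = c(2.3, 23.6),
                 SWI = c(4.647, 11.029), DND = c(81, 46908),
                 AGLB = c(31, 328.8), EVI_wet = c(0.37, 0.71),
                 EVI_dry = c(0.43, 0.78), EVI_diff = c(-0.16, 0.30))
  for (nm in names(ranges)) {
    v <- st$layers[[nm]]
    expect_true(all(v >= ranges[[nm]][1] & v <= ranges[[nm]][2]),
                info = nm)
  }
  basins <- unique(as.vector(st$basin))
  expect_true(length(basins) %in% 2:3)
  expect_error(generate_covariate_stack(sim_config(), grid_spec(
    n_rows = 0, n_cols = 5)), "at least one cell")
})

test_that("latent surfaces are valid probability/rate fields", {
  land <- default_landscape()
  expect_true(all(land$surfaces$presence_prob >= 0 &
                    land$surfaces$presence_prob <= 1))
  expect_true(all(land$surfaces$cond_biomass >= 0))
  expect_true(all(is.finite(land$surfaces$cond_biomass)))

  # zero effects + zero GRF sill -> constant surfaces
  flat <- sim_config(seed = 5,
                     presence = list(intercept = 0.5, effects = c(),
                                     grf = list(psill = 0, range = 100,
                                                nugget = 0)),
                     biomass = list(intercept = log(20), effects = c(),
                                    grf = list(psill = 0, range = 100,
                                               nugget = 0),
                                    sigma_obs = 0.5))
  s <- simulate_fruitfall_surface(land$stack, flat)
  expect_equal(max(s$presence_prob) - min(s$presence_prob), 0)
  expect_equal(unique(as.vector(s$cond_biomass)), 20)
  expect_error(sim_config(presence = list(intercept = Inf, effects = c(),
                                          grf = list(psill = 1, range = 1,
                                                     nugget = 0))),
               "finite")
})

test_that("latent biomass field's variogram recovers the configured range", {
  # 400-cell rasters carry few independent range-sized patches, so the
  # check uses the median over replicate landscapes
  est <- vapply(1:7, function(s) {
    cfg <- sim_config(seed = 100 + s,
                      biomass = list(intercept = log(40), effects = c(),
                                     grf = list(psill = 1, range = 300,
                                                nugget = 0),
                                     sigma_obs = 0.5))
    st <- generate_covariate_stack(cfg, grid_spec())
    surf <- simulate_fruitfall_surface(st, cfg)
    cc <- cell_centers(st$grid)
    fit_variogram_model(
      empirical_variogram(cbind(cc$x, cc$y),
                          log(as.vector(surf$cond_biomass)),
                          max_lag = 1500),
      family = "exponential")$range
  }, 0)
  expect_gt(median(est), 0.75 * 300)
  expect_lt(median(est), 1.25 * 300)
})

test_that("survey design reproduces the 30-point / 90-plot layout", {
  land <- default_landscape()
  des <- land$design
  expect_equal(nrow(des$points), 30)
  expect_equal(nrow(des$plots), 90)
  expect_true(all(table(des$plots$sample_point_id) == 3))
  expect_true(all(des$plots$area_m2 >= 400 & des$plots$area_m2 <= 600))
  expect_equal(mean(des$plots$area_m2), 490.7)
  expect_equal(round(sum(des$plots$area_m2) / 1e4, 2), 4.42)
  expect_true(all(des$plots$area_m2[des$plots$plot_kind == "trail"] ==
                    500))
  inside <- des$plots$x >= 0 & des$plots$x <= 5000 &
    des$plots$y >= 0 & des$plots$y <= 5000
  expect_true(all(inside))
  expect_error(sample_survey_design(grid_spec(n_rows = 10, n_cols = 10,
                                              cell_size = 100)),
               "too small")
})

test_that("zero-intensity configuration yields 90 empty plots", {
  cfg <- sim_config(seed = 9,
                    presence = list(intercept = -50, effects = c(),
                                    grf = list(psill = 0, range = 100,
                                               nugget = 0)),
                    background = list(n_species = 40L,
                                      mean_species_per_plot = 0,
                                      mean_count_per_occurrence = 100,
                                      count_sdlog = 0.5,
                                      mass_meanlog = log(5),
                                      mass_sdlog = 0.9))
  land <- simulate_landscape(cfg)
  expect_equal(nrow(land$observations), 0)
  r <- build_response_table(land$observations, land$design$plots,
                            land$species_mass, land$stack,
                            cfg$dominant_species, 2)
  expect_equal(nrow(r), 90)
  expect_true(all(r$presence == 0))
  expect_true(all(r$biomass == 0))
})

test_that("default calibration matches the survey's summary statistics", {
  # replicate landscapes; targets: overall biomass within +-30% of
  # 44.8 kg/ha/month, dominant biomass share within 15 points of 64%
  n_rep <- 40
  stats <- vapply(seq_len(n_rep), function(s) {
    land <- simulate_landscape(sim_config(seed = 5000 + s))
    r <- build_response_table(land$observations, land$design$plots,
                              land$species_mass, land$stack,
                              land$config$dominant_species, 2)
    cnt <- apply_inclusion_rules(land$observations)
    dom <- species_dominance_table(cnt, land$species_mass)
    i <- dom$species == land$config$dominant_species
    c(overall = mean(r$biomass_overall_monthly),
      presence = sum(r$presence),
      bshare = if (any(i)) dom$biomass_share_pct[i] else 0,
      rich = mean(r$richness_ha))
  }, numeric(4))
  m <- rowMeans(stats)
  expect_gt(m["overall"], 44.8 * 0.7)
  expect_lt(m["overall"], 44.8 * 1.3)
  expect_gt(m["bshare"], 64 - 15)
  expect_lt(m["bshare"], 64 + 15)
  expect_gt(m["presence"], 62 * 0.8)
  expect_lt(m["presence"], 62 * 1.2)
  expect_gt(m["rich"], 44.6 * 0.7)
  expect_lt(m["rich"], 44.6 * 1.3)
})

test_that("iid plot values stay inside the CSR envelope", {
  # zero covariate effects and zero GRF sill -> values i.i.d. across plots
  land <- default_landscape()
  xy <- cbind(land$design$plots$x, land$design$plots$y)
  set.seed(31)
  covs <- vapply(1:20, function(i)
    envelope_coverage(csr_envelope(xy, rnorm(90), n_perm = 199,
                                   seed = i)), 0)
  expect_gte(mean(covs), 0.9)
})
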