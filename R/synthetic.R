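#' Simulation configuration for the synthetic landscape
#'
#' Collects every tunable of the synthetic-data generator in one seeded,
#' self-describing object. The defaults reproduce the statistical structure
#' of the motivating survey: a 5 x 5 km grid sampled at 30 points (three
#' plots each, ~4.42 ha total), a single dominant masting species present in
#' roughly 62 of 90 plots contributing ~43% of fruit counts and ~64% of dry
#' biomass, an overall fruit-fall rate around 44.8 kg ha^-1 month^-1 with a
#' heavy right tail, richness near 44.6 species ha^-1, and covariate layers
#' confined to the study-area ranges.
#'
#' @param seed Integer; the single source of randomness for every generator
#'   stage (covariates, latent surfaces, design jitter, observations).
#' @param n_survey_months Length of the survey window (months) over which
#'   simulated counts accumulate.
#' @param dominant_species Name of the focal masting species.
#' @param dominant_mass_g Mean dry mass (g) of one fruit of the focal
#'   species.
#' @param dominant_seed_mass_g Mean dry mass (g) of its seed.
#' @param presence Hurdle occurrence part: list with `intercept` (logit
#'   scale), `effects` (named vector of covariate slopes on standardized
#'   layers), and `grf` (list `psill`, `range`, `nugget`) for the latent
#'   Gaussian random field on the logit scale.
#' @param biomass Hurdle positive part: same structure on the log scale of
#'   the conditional biomass rate (kg ha^-1 month^-1), plus `sigma_obs`,
#'   the plot-level log-normal dispersion around the latent rate.
#' @param background Background community: list with `n_species`,
#'   `mean_species_per_plot` (expected background richness per plot),
#'   `mean_count_per_occurrence` (expected eligible fruits per
#'   plot-occurrence), `count_sdlog` (log-normal count dispersion),
#'   `mass_meanlog`/`mass_sdlog` (log-normal fruit dry-mass spread, g).
#' @param status_props Proportions splitting eligible counts between
#'   `fresh` and `partially_eaten`, plus mean rates (fraction of the
#'   eligible count) of excluded `rotten`, `dried` and `germinating`
#'   tallies added as decoys.
#' @param grf_family Covariance family of all latent fields.
#'
#' @return An object of class `sim_config` (a list).
#' @export
sim_config <- function(seed = 42L,
                       n_survey_months = 2L,
                       dominant_species = "Vouacapoua americana",
                       dominant_mass_g = 18.2,
                       dominant_seed_mass_g = 16.2,
                       presence = list(
                         intercept = 0.93,
                         effects = c(),
                         grf = list(psill = 0.8, range = 70, nugget = 0)
                       ),
                       biomass = list(
                         intercept = log(41.4),
                         effects = c(),
                         grf = list(psill = 0.35, range = 70, nugget = 0),
                         sigma_obs = 0.61
                       ),
                       background = list(
                         n_species = 40L,
                         mean_species_per_plot = 1.5,
                         mean_count_per_occurrence = 136,
                         count_sdlog = 0.6,
                         mass_meanlog = log(5),
                         mass_sdlog = 0.9
                       ),
                       status_props = list(
                         fresh = 0.85, partially_eaten = 0.15,
                         rotten = 0.08, dried = 0.03, germinating = 0.04
                       ),
                       grf_family = "exponential") {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  for (part in list(presence, biomass)) {
    if (!all(is.finite(c(part$intercept, part$effects))))
      stop("effect sizes and intercepts must be finite", call. = FALSE)
    stopifnot(part$grf$psill >= 0, part$grf$range > 0, part$grf$nugget >= 0)
  }
  cfg <- list(seed = as.integer(seed),
              n_survey_months = as.integer(n_survey_months),
              dominant_species = dominant_species,
              dominant_mass_g = dominant_mass_g,
              dominant_seed_mass_g = dominant_seed_mass_g,
              presence = presence, biomass = biomass,
              background = background, status_props = status_props,
              grf_family = grf_family)
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("sim_config: seed %d, %d-month survey\n", x$seed,
              x$n_survey_months))
  cat(sprintf("  focal species '%s' (%.1f g/fruit)\n", x$dominant_species,
              x$dominant_mass_g))
  cat(sprintf("  presence GRF psill %.2f range %.0f m; biomass GRF psill %.2f range %.0f m\n",
              x$presence$grf$psill, x$presence$grf$range,
              x$biomass$grf$psill, x$biomass$grf$range))
  invisible(x)
}

#' Simulate a Gaussian random field at arbitrary locations
#'
#' Exact simulation by Cholesky factorisation of the covariance matrix,
#' suitable for the few hundred locations used here. Covariance is
#' `psill * exp(-h / range)` (exponential) or the spherical equivalent,
#' plus `nugget` on the diagonal.
#'
#' @param coords Two-column coordinate matrix (m).
#' @param psill Partial sill (structured variance).
#' @param range Range parameter (m); for the exponential family the
#'   practical range is about `3 * range`.
#' @param nugget Unstructured variance added on the diagonal.
#' @param family `"exponential"` or `"spherical"`.
#' @return Numeric vector, one draw per location (mean zero). Uses the
#'   current RNG state; seed before calling for reproducibility.
#' @export
sim_gaussian_field <- function(coords, psill, range, nugget = 0,
                               family = "exponential") {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  stopifnot(psill >= 0, nugget >= 0, range > 0)
  if (psill == 0 && nugget == 0) return(numeric(n))
  if (psill == 0) return(stats::rnorm(n, 0, sqrt(nugget)))
  d <- as.matrix(stats::dist(coords))
  cv <- switch(family,
    exponential = psill * exp(-d / range),
    spherical = psill * ifelse(d >= range, 0,
                               1 - 1.5 * d / range + 0.5 * (d / range)^3),
    stop(sprintf("unknown covariance family '%s'", family), call. = FALSE))
  diag(cv) <- psill + nugget + 1e-8 * psill
  L <- chol(cv)
  as.vector(crossprod(L, stats::rnorm(n)))
}

# Affine rescale to a target mean/sd, then clamp to [lo, hi].
rescale_clamp <- function(z, mean, sd, lo, hi) {
  s <- stats::sd(z)
  z <- if (is.na(s) || s == 0) rep(mean, length(z)) else
    mean + sd * (z - base::mean(z)) / s
  pmin(hi, pmax(lo, z))
}

# Central-difference gradients of a [row, col] matrix (row 1 = south).
# One-sided at the edges. Returns d/dx (west->east) and d/dy (south->north).
grid_gradients <- function(m, cell_size) {
  nr <- nrow(m); nc <- ncol(m)
  east <- m[, c(2:nc, nc), drop = FALSE]
  west <- m[, c(1, 1:(nc - 1)), drop = FALSE]
  north <- m[c(2:nr, nr), , drop = FALSE]
  south <- m[c(1, 1:(nr - 1)), , drop = FALSE]
  span_x <- matrix(2 * cell_size, nr, nc)
  span_x[, c(1, nc)] <- cell_size
  span_y <- matrix(2 * cell_size, nr, nc)
  span_y[c(1, nr), ] <- cell_size
  list(gx = (east - west) / span_x, gy = (north - south) / span_y)
}

#' Generate the synthetic covariate raster stack
#'
#' Builds eleven spatially autocorrelated layers on the grid: a Gaussian
#' random-field altitude surface; slope, aspect, topographic wetness (TWI),
#' SAGA wetness (SWI) and distance-to-drainage (DND) derived
#' deterministically from it (finite-difference gradients; channels at the
#' lowest altitudes); independent fields for above-ground live biomass
#' (AGLB) and wet-season EVI; dry-season EVI as wet EVI plus a seasonal
#' difference field; and `EVI_diff = EVI_dry - EVI_wet` by construction.
#' Each layer is rescaled to the study-area mean/SD and clamped inside the
#' study-area range. A three-region Voronoi partition provides the basin
#' raster.
#'
#' @param config A [sim_config()].
#' @param grid A [grid_spec()].
#' @return A [covariate_stack()] with layers `Altitude`, `Slope`, `Aspect`,
#'   `TWI`, `SWI`, `DND`, `AGLB`, `EVI_wet`, `EVI_dry`, `EVI_diff`.
#' @export
generate_covariate_stack <- function(config, grid = grid_spec()) {
  stopifnot(inherits(config, "sim_config"), inherits(grid, "grid_spec"))
  if (grid$n_rows * grid$n_cols == 0)
    stop("degenerate grid: zero cells", call. = FALSE)
  set.seed(config$seed)
  cc <- cell_centers(grid)
  xy <- cbind(cc$x, cc$y)
  nr <- grid$n_rows; nc <- grid$n_cols
  as_mat <- function(v) matrix(v, nrow = nr, ncol = nc)

  # altitude: broad field + finer roughness so slopes are realistic
  alt_z <- sim_gaussian_field(xy, 1, 400, family = config$grf_family) +
    0.45 * sim_gaussian_field(xy, 1, 120, family = config$grf_family)
  altitude <- as_mat(rescale_clamp(alt_z, 117.2, 14.5, 67, 182))

  gr <- grid_gradients(altitude, grid$cell_size)
  slope_pct <- pmin(19.1, pmax(1.3, 100 * sqrt(gr$gx^2 + gr$gy^2)))
  aspect <- (180 / pi * atan2(-gr$gx, -gr$gy)) %% 360
  aspect <- pmin(347.1, pmax(21.1, aspect))

  # synthetic channel network: lowest 12% of cells; DND = distance to it
  ch <- altitude <= stats::quantile(altitude, 0.12)
  ch_xy <- xy[as.vector(ch), , drop = FALSE]
  dnd <- sqrt(outer(cc$x, ch_xy[, 1], "-")^2 +
              outer(cc$y, ch_xy[, 2], "-")^2)
  dnd <- as_mat(pmin(46908, pmax(81, apply(dnd, 1, min))))

  twi <- rescale_clamp(-log(slope_pct / 100 + 0.005) - dnd / 2000,
                       13.7, 4, 2.3, 23.6)
  swi <- rescale_clamp(-log(slope_pct / 100 + 0.02) - dnd / 4000,
                       7.549, 0.9, 4.647, 11.029)

  aglb <- as_mat(rescale_clamp(
    sim_gaussian_field(xy, 1, 300, family = config$grf_family),
    277.1, 25, 203, 328.8))
  evi_wet <- as_mat(rescale_clamp(
    sim_gaussian_field(xy, 1, 300, family = config$grf_family),
    0.49, 0.03, 0.43, 0.56))
  evi_d <- as_mat(rescale_clamp(
    sim_gaussian_field(xy, 1, 300, family = config$grf_family),
    0.105, 0.03, 0.01, 0.19))
  evi_dry <- evi_wet + evi_d

  # basins: Voronoi regions of three fixed seed points (contiguous)
  bseed <- cbind(grid$origin_x + c(0.20, 0.65, 0.80) * grid$extent_x,
                 grid$origin_y + c(0.75, 0.25, 0.85) * grid$extent_y)
  bd <- sqrt(outer(cc$x, bseed[, 1], "-")^2 +
             outer(cc$y, bseed[, 2], "-")^2)
  basin <- as_mat(max.col(-bd))

  covariate_stack(grid, list(
    Altitude = altitude, Slope = as_mat(slope_pct), Aspect = as_mat(aspect),
    TWI = as_mat(twi), SWI = as_mat(swi), DND = dnd, AGLB = aglb,
    EVI_wet = evi_wet, EVI_dry = evi_dry, EVI_diff = evi_dry - evi_wet
  ), basin)
}

#' Simulate the latent fruit-fall surfaces
#'
#' Produces the two latent rasters of the hurdle model: the occurrence
#' probability surface (inverse-logit of a linear combination of
#' standardized covariates plus a Gaussian random field) and the
#' conditional biomass rate surface (exponential of the analogous log-scale
#' predictor, kg ha^-1 month^-1). With all effects zero and zero GRF sill
#' both surfaces are constant.
#'
#' @param stack A [covariate_stack()].
#' @param config A [sim_config()]; `presence$effects` / `biomass$effects`
#'   are named vectors matching layer names.
#' @return An object of class `fruitfall_surfaces`: list with `grid`,
#'   `presence_prob` and `cond_biomass` matrices.
#' @export
simulate_fruitfall_surface <- function(stack, config) {
  stopifnot(inherits(stack, "covariate_stack"), inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  cc <- cell_centers(stack$grid)
  xy <- cbind(cc$x, cc$y)
  nr <- stack$grid$n_rows; nc <- stack$grid$n_cols

  linpred <- function(part) {
    eta <- rep(part$intercept, nr * nc)
    effs <- part$effects
    if (length(effs)) {
      if (!all(names(effs) %in% names(stack$layers)))
        stop("effect names must match covariate layers", call. = FALSE)
      for (nm in names(effs)) {
        v <- as.vector(stack$layers[[nm]])
        s <- stats::sd(v)
        z <- if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
        eta <- eta + effs[[nm]] * z
      }
    }
    eta + sim_gaussian_field(xy, part$grf$psill, part$grf$range,
                             part$grf$nugget, config$grf_family)
  }

  p <- stats::plogis(linpred(config$presence))
  mu <- exp(linpred(config$biomass) - config$biomass$grf$psill / 2)
  structure(list(grid = stack$grid,
                 presence_prob = matrix(p, nr, nc),
                 cond_biomass = matrix(mu, nr, nc)),
            class = "fruitfall_surfaces")
}

#' Lay out the 30-point, 90-plot survey design
#'
#' Places 30 sample points on an approximately 1-km lattice (5 columns at
#' 1000 m, 6 rows at 920 m, centred in the grid) and attaches three plots
#' per point: one contour-following "permanent" plot at the point and two
#' linear trail plots offset 150 m either side. Trail plots are exactly
#' 500 m^2 (2 x 250 m); permanent-plot areas are 472.1 m^2 plus centred
#' seeded jitter, so the 90-plot mean is exactly 490.7 m^2 and the total
#' sampled area 4.4163 ha.
#'
#' @param grid A [grid_spec()] at least 5 x 5 km.
#' @param config A [sim_config()] (seeds the area jitter).
#' @return An object of class `survey_design`: list with `points` (30 rows:
#'   `point_id`, `x`, `y`) and `plots` (90 rows: `plot_id`,
#'   `sample_point_id`, `plot_kind`, `x`, `y`, `area_m2`).
#' @export
sample_survey_design <- function(grid, config = sim_config()) {
  stopifnot(inherits(grid, "grid_spec"))
  if (grid$extent_x < 5000 || grid$extent_y < 5000)
    stop("grid too small to host the 1-km survey lattice (need >= 5 x 5 km)",
         call. = FALSE)
  set.seed(config$seed + 2L)
  px <- grid$origin_x + grid$extent_x / 2 + (-2:2) * 1000
  py <- grid$origin_y + grid$extent_y / 2 + seq(-2.5, 2.5) * 920
  pts <- expand.grid(x = px, y = py)
  pts <- data.frame(point_id = sprintf("SP%02d", seq_len(nrow(pts))),
                    x = pts$x, y = pts$y)

  jit <- stats::runif(nrow(pts), -45, 45)
  jit <- jit - mean(jit)  # centre so the overall mean area is exact
  plots <- do.call(rbind, lapply(seq_len(nrow(pts)), function(i) {
    data.frame(
      plot_id = sprintf("%s-%s", pts$point_id[i], c("perm", "t1", "t2")),
      sample_point_id = pts$point_id[i],
      plot_kind = c("permanent", "trail", "trail"),
      x = pts$x[i] + c(0, -150, 150),
      y = pts$y[i],
      area_m2 = c(472.1 + jit[i], 500, 500)
    )
  }))
  rownames(plots) <- NULL
  structure(list(points = pts, plots = plots, grid = grid),
            class = "survey_design")
}

#' @export
print.survey_design <- function(x, ...) {
  cat(sprintf(
    "survey_design: %d sample points, %d plots, %.4f ha sampled\n",
    nrow(x$points), nrow(x$plots), sum(x$plots$area_m2) / 1e4))
  invisible(x)
}

# Fixed background species pool: masses from log-normal quantiles (so the
# pool is a constant lookup table, not a random draw), geometric relative
# abundances.
default_species_pool <- function(background) {
  n <- background$n_species
  qq <- (seq_len(n) - 0.5) / n
  mass <- round(stats::qlnorm(qq, background$mass_meanlog,
                              background$mass_sdlog), 2)
  # shuffle deterministically so mass is unrelated to abundance rank
  ord <- order(sin(7.3 * seq_len(n)))
  ab <- 0.85^(seq_len(n) - 1)
  data.frame(species = sprintf("Species_%02d", seq_len(n)),
             mean_dry_mass_g = mass[ord],
             rel_abundance = ab / sum(ab))
}

#' Simulate plot-level fruit-fall observations
#'
#' Draws per-plot, per-species fruit tallies from the hurdle model
#' evaluated at each plot centroid. The focal species follows
#' Bernoulli(presence probability) occurrence; given occurrence its
#' biomass rate is the latent conditional rate times log-normal plot noise,
#' converted to a Poisson fruit count via area, survey length and fruit
#' mass. Background species occur independently with abundance-weighted
#' probabilities and log-normal-Poisson counts. Eligible counts are split
#' into `fresh` and `partially_eaten` tallies; additional `rotten`, `dried`
#' and `germinating` tallies are appended (they are excluded again by the
#' inclusion rules downstream).
#'
#' @param design A [sample_survey_design()] result.
#' @param surfaces A [simulate_fruitfall_surface()] result.
#' @param config A [sim_config()].
#' @return A list with `observations` (long data.frame: `plot_id`,
#'   `species`, `status`, `count`, `survey_month`, `removable`) and
#'   `species_mass` (data.frame: `species`, `mean_dry_mass_g`, `n_weighed`,
#'   `removable`).
#' @export
simulate_plot_observations <- function(design, surfaces, config) {
  stopifnot(inherits(design, "survey_design"),
            inherits(surfaces, "fruitfall_surfaces"),
            inherits(config, "sim_config"))
  set.seed(config$seed + 3L)
  plots <- design$plots
  rc <- point_to_cell(surfaces$grid, plots$x, plots$y)
  idx <- cbind(rc$row, rc$col)
  p <- surfaces$presence_prob[idx]
  mu <- surfaces$cond_biomass[idx]
  pool <- default_species_pool(config$background)
  occ_p <- pmin(0.95, config$background$mean_species_per_plot *
                        pool$rel_abundance)
  sp <- config$status_props

  split_status <- function(plot_id, species, n_elig, month, removable) {
    if (n_elig <= 0) return(NULL)
    fresh <- stats::rbinom(1, n_elig, sp$fresh)
    extras <- stats::rpois(3, n_elig * c(sp$rotten, sp$dried,
                                         sp$germinating))
    counts <- c(fresh, n_elig - fresh, extras)
    keep <- counts > 0
    if (!any(keep)) return(NULL)
    data.frame(plot_id = plot_id, species = species,
               status = c("fresh", "partially_eaten", "rotten", "dried",
                          "germinating")[keep],
               count = counts[keep], survey_month = month,
               removable = removable)
  }

  rows <- vector("list", nrow(plots))
  for (i in seq_len(nrow(plots))) {
    out <- list()
    # focal species hurdle
    if (stats::rbinom(1, 1, p[i]) == 1) {
      rate <- mu[i] * stats::rlnorm(1, -config$biomass$sigma_obs^2 / 2,
                                    config$biomass$sigma_obs)
      grams <- rate * (plots$area_m2[i] / 1e4) * config$n_survey_months * 1e3
      n_fruit <- stats::rpois(1, grams / config$dominant_mass_g)
      out[[length(out) + 1L]] <- split_status(
        plots$plot_id[i], config$dominant_species, n_fruit, 1L, TRUE)
    }
    # background community
    present <- which(stats::runif(nrow(pool)) < occ_p)
    for (s in present) {
      lam <- config$background$mean_count_per_occurrence *
        stats::rlnorm(1, -config$background$count_sdlog^2 / 2,
                      config$background$count_sdlog)
      n_fruit <- stats::rpois(1, lam)
      out[[length(out) + 1L]] <- split_status(
        plots$plot_id[i], pool$species[s], n_fruit, 1L, FALSE)
    }
    rows[[i]] <- do.call(rbind, out)
  }
  obs <- do.call(rbind, rows)
  if (is.null(obs))
    obs <- data.frame(plot_id = character(), species = character(),
                      status = character(), count = integer(),
                      survey_month = integer(), removable = logical())
  rownames(obs) <- NULL
  masses <- rbind(
    data.frame(species = config$dominant_species,
               mean_dry_mass_g = config$dominant_mass_g, n_weighed = 20L,
               removable = TRUE),
    data.frame(species = pool$species, mean_dry_mass_g = pool$mean_dry_mass_g,
               n_weighed = pmin(30L, 5L + 2L * seq_len(nrow(pool))),
               removable = FALSE))
  rownames(masses) <- NULL
  list(observations = obs, species_mass = masses)
}

#' Generate a complete synthetic landscape and survey
#'
#' Convenience wrapper chaining [generate_covariate_stack()],
#' [simulate_fruitfall_surface()], [sample_survey_design()] and
#' [simulate_plot_observations()].
#'
#' @param config A [sim_config()].
#' @param grid A [grid_spec()].
#' @return A list with `stack`, `surfaces`, `design`, `observations`,
#'   `species_mass` and the `config`.
#' @export
simulate_landscape <- function(config = sim_config(), grid = grid_spec()) {
  stack <- generate_covariate_stack(config, grid)
  surfaces <- simulate_fruitfall_surface(stack, config)
  design <- sample_survey_design(grid, config)
  obs <- simulate_plot_observations(design, surfaces, config)
  list(stack = stack, surfaces = surfaces, design = design,
       observations = obs$observations, species_mass = obs$species_mass,
       config = config)
}
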