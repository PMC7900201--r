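# Shared fixtures, built in code. The default landscape is cached per test
# file so the generator runs once.

landscape_cache <- new.env(parent = emptyenv())

default_landscape <- function(seed = 101) {
  key <- as.character(seed)
  if (is.null(landscape_cache[[key]]))
    landscape_cache[[key]] <- simulate_landscape(sim_config(seed = seed))
  landscape_cache[[key]]
}

default_responses <- function(seed = 101) {
  key <- paste0("resp-", seed)
  if (is.null(landscape_cache[[key]])) {
    land <- default_landscape(seed)
    landscape_cache[[key]] <- build_response_table(
      land$observations, land$design$plots, land$species_mass, land$stack,
      focal_species = land$config$dominant_species, n_survey_months = 2)
  }
  landscape_cache[[key]]
}

# O(n^2) all-pairs semivariance oracle, independent of the package's
# vectorised implementation.
brute_force_variogram <- function(coords, values, n_bins, max_lag) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  bw <- max_lag / n_bins
  g <- numeric(n_bins)
  np <- integer(n_bins)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- sqrt(sum((coords[i, ] - coords[j, ])^2))
    b <- if (d == max_lag) n_bins else floor(d / bw) + 1
    if (d > 0 && b <= n_bins) {
      np[b] <- np[b] + 1L
      g[b] <- g[b] + (values[i] - values[j])^2
    }
  }
  list(gamma = ifelse(np > 0, g / (2 * np), NA_real_), n_pairs = np)
}

# Response table with known covariate structure for model tests (no
# spatial machinery involved).
linear_fixture <- function(n = 80, seed = 1, noise = 0) {
  set.seed(seed)
  d <- data.frame(x1 = runif(n), x2 = runif(n), x3 = runif(n))
  d$y <- 2 + 3 * d$x1 - 1.5 * d$x2 + rnorm(n, 0, noise)
  d
}
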