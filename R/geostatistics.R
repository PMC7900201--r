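#' Empirical (semi)variogram
#'
#' Method-of-moments semivariance estimator: for every pair of points whose
#' separation distance falls in a lag bin,
#' gamma(h) = sum (z_i - z_j)^2 / (2 N(h)). Bins are half-open
#' `[lower, upper)` except the last, which is closed at `max_lag` so the
#' largest admitted pair is retained.
#'
#' @param coords Two-column matrix (or data.frame) of projected coordinates
#'   in metres.
#' @param values Numeric vector of the response at each location.
#' @param n_bins Number of equal-width lag bins (default 15).
#' @param max_lag Largest separation distance considered; default half the
#'   maximum pairwise distance, common variogram practice.
#' @return An object of class `empirical_variogram`: data.frame-like list
#'   with `lag` (bin centres, m), `gamma`, `n_pairs`, plus attributes
#'   `max_lag`, `bin_width`.
#' @export
#' @examples
#' set.seed(1)
#' xy <- cbind(runif(40, 0, 1000), runif(40, 0, 1000))
#' ev <- empirical_variogram(xy, rnorm(40))
#' ev$gamma
empirical_variogram <- function(coords, values, n_bins = 15, max_lag = NULL) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 2, nrow(coords) == length(values),
            all(is.finite(coords)), all(is.finite(values)))
  n <- nrow(coords)
  if (n < 2) stop("need at least two points", call. = FALSE)
  d <- stats::dist(coords)
  if (max(d) == 0) stop("all points are coincident", call. = FALSE)
  if (is.null(max_lag)) max_lag <- max(d) / 2
  stopifnot(max_lag > 0, n_bins >= 1)
  sq <- stats::dist(values)^2
  bw <- max_lag / n_bins
  bin <- pmin(floor(as.vector(d) / bw) + 1L, n_bins + 1L)
  bin[as.vector(d) == max_lag] <- n_bins  # close the last bin at max_lag
  keep <- bin <= n_bins & as.vector(d) > 0
  np <- tabulate(bin[keep], nbins = n_bins)
  ssq <- as.vector(rowsum(as.vector(sq)[keep], bin[keep],
                          reorder = TRUE))
  gamma <- rep(NA_real_, n_bins)
  gamma[sort(unique(bin[keep]))] <- ssq / (2 * np[np > 0])
  gamma[np == 0] <- NA_real_
  structure(
    list(lag = (seq_len(n_bins) - 0.5) * bw, gamma = gamma, n_pairs = np,
         max_lag = max_lag, bin_width = bw),
    class = "empirical_variogram")
}

#' @export
print.empirical_variogram <- function(x, ...) {
  cat(sprintf("empirical_variogram: %d lag bins to %.1f m\n",
              length(x$lag), x$max_lag))
  print(data.frame(lag = round(x$lag, 1), gamma = signif(x$gamma, 4),
                   n_pairs = x$n_pairs))
  invisible(x)
}

#' Presence/absence indicator transform
#'
#' Maps a nonnegative response (e.g. plot biomass) to the 0/1 occupancy
#' indicator used for the presence variogram and presence models.
#'
#' @param values Numeric vector, all `>= 0`.
#' @return Integer vector of 0/1.
#' @export
indicator_transform <- function(values) {
  stopifnot(is.numeric(values), all(is.finite(values)))
  if (any(values < 0)) stop("values must be nonnegative", call. = FALSE)
  as.integer(values > 0)
}

# Theoretical semivariance of the supported model families.
# Exponential uses gamma(h) = nugget + psill * (1 - exp(-h / range)); its
# practical range (95% of the sill) is about 3 * range.
variogram_gamma <- function(h, family, nugget, psill, range) {
  structural <- switch(family,
    spherical = ifelse(h >= range, psill,
                       psill * (1.5 * h / range - 0.5 * (h / range)^3)),
    exponential = psill * (1 - exp(-h / range)),
    stop(sprintf("unknown variogram family '%s'", family), call. = FALSE))
  ifelse(h > 0, nugget + structural, 0)
}

#' Fit a variogram model by weighted least squares
#'
#' Estimates nugget, partial sill and range for a spherical or exponential
#' model by minimising the pair-count-weighted sum of squared deviations
#' from the empirical semivariances (weights N(h)), with all parameters
#' constrained nonnegative. `family = "best"` (default) fits both families
#' and returns the lower weighted SSE.
#'
#' @param ev An [empirical_variogram()].
#' @param family `"spherical"`, `"exponential"` or `"best"`.
#' @return An object of class `variogram_model` with elements `family`,
#'   `nugget`, `psill`, `range`, `sill` (= nugget + psill), `wsse` and the
#'   empirical variogram used.
#' @details The optimiser is L-BFGS-B from several starting points (range
#'   at 1/4, 1/2 and the full max lag; nugget at 0 and half the mean
#'   semivariance). For the exponential family `range` is the distance
#'   parameter; the practical range is about three times it.
#' @export
fit_variogram_model <- function(ev, family = c("best", "spherical",
                                               "exponential")) {
  stopifnot(inherits(ev, "empirical_variogram"))
  family <- match.arg(family)
  ok <- !is.na(ev$gamma) & ev$n_pairs > 0
  if (sum(ok) < 3) stop("need at least 3 non-empty lag bins", call. = FALSE)
  h <- ev$lag[ok]; g <- ev$gamma[ok]; w <- ev$n_pairs[ok]

  fit_one <- function(fam) {
    obj <- function(p) {
      gg <- variogram_gamma(h, fam, p[1], p[2], p[3])
      sum(w * (g - gg)^2)
    }
    gbar <- stats::weighted.mean(g, w)
    starts <- expand.grid(nug = c(0, gbar / 2),
                          ps = c(gbar, gbar / 2, max(g)),
                          rg = c(0.25, 0.5, 1) * ev$max_lag)
    best <- NULL
    for (i in seq_len(nrow(starts))) {
      res <- tryCatch(
        stats::optim(as.numeric(starts[i, ]), obj, method = "L-BFGS-B",
                     lower = c(0, 0, 1e-6 * ev$max_lag),
                     upper = c(Inf, Inf, 10 * ev$max_lag)),
        error = function(e) NULL)
      if (!is.null(res) && (is.null(best) || res$value < best$value))
        best <- res
    }
    if (is.null(best))
      stop(sprintf("variogram optimisation failed for family '%s'", fam),
           call. = FALSE)
    list(family = fam, nugget = best$par[1], psill = best$par[2],
         range = best$par[3], wsse = best$value,
         convergence = best$convergence)
  }

  fams <- if (family == "best") c("spherical", "exponential") else family
  fits <- lapply(fams, fit_one)
  fit <- fits[[which.min(vapply(fits, `[[`, 0, "wsse"))]]
  fit$sill <- fit$nugget + fit$psill
  fit$empirical <- ev
  class(fit) <- "variogram_model"
  fit
}

#' @export
print.variogram_model <- function(x, ...) {
  cat(sprintf(
    "variogram_model (%s): nugget %.4g, partial sill %.4g, range %.1f m\n",
    x$family, x$nugget, x$psill, x$range))
  cat(sprintf("  sill %.4g, nugget/sill %.2f, weighted SSE %.4g\n",
              x$sill, if (x$sill > 0) x$nugget / x$sill else NA, x$wsse))
  invisible(x)
}

#' Predict model semivariance at given lags
#'
#' @param object A [fit_variogram_model()] result.
#' @param h Numeric lags (m).
#' @param ... Ignored.
#' @return Semivariance gamma(h).
#' @export
predict.variogram_model <- function(object, h, ...) {
  variogram_gamma(h, object$family, object$nugget, object$psill,
                  object$range)
}

#' Nugget-to-sill ratio
#'
#' Fraction of the total sill attributable to the nugget (micro-scale or
#' non-spatial variance): the conventional summary of how much of the
#' variation is spatially unstructured.
#'
#' @param model A `variogram_model`.
#' @return A fraction in `[0, 1]`.
#' @export
nugget_sill_ratio <- function(model) {
  stopifnot(inherits(model, "variogram_model"))
  if (model$sill <= 0) stop("sill is zero; ratio undefined", call. = FALSE)
  model$nugget / model$sill
}

#' Complete-spatial-randomness envelope by permutation
#'
#' Builds a null band for the empirical variogram by permuting the observed
#' values across the fixed locations `n_perm` times and taking pointwise
#' quantiles of the permuted semivariances at every lag. Values inside the
#' band are consistent with complete spatial randomness of the values given
#' the point pattern.
#'
#' @param coords Two-column coordinate matrix (m).
#' @param values Response values.
#' @param n_perm Number of permutations (default 999).
#' @param quantiles Lower/upper pointwise quantiles (default 2.5% / 97.5%);
#'   use `c(0, 1)` for a min-max band.
#' @param seed Integer seed for the permutations.
#' @param n_bins,max_lag Passed to [empirical_variogram()]; the observed and
#'   permuted variograms share the binning.
#' @return An object of class `csr_envelope` with `lag`, `lower`, `upper`,
#'   `observed` (the observed [empirical_variogram()]), `n_perm`,
#'   `quantiles`.
#' @export
csr_envelope <- function(coords, values, n_perm = 999,
                         quantiles = c(0.025, 0.975), seed = 1,
                         n_bins = 15, max_lag = NULL) {
  stopifnot(n_perm >= 1, length(quantiles) == 2,
            all(quantiles >= 0 & quantiles <= 1),
            quantiles[1] <= quantiles[2])
  obs <- empirical_variogram(coords, values, n_bins = n_bins,
                             max_lag = max_lag)
  coords <- as.matrix(coords)
  n <- nrow(coords)
  d <- as.vector(stats::dist(coords))
  bw <- obs$bin_width
  bin <- pmin(floor(d / bw) + 1L, n_bins + 1L)
  bin[d == obs$max_lag] <- n_bins
  keep <- bin <= n_bins & d > 0
  bin <- bin[keep]
  np <- tabulate(bin, nbins = n_bins)
  # index pairs once; per permutation only the squared differences change
  pair_i <- rep(seq_len(n - 1), times = (n - 1):1)
  pair_j <- unlist(lapply(seq_len(n - 1), function(i) (i + 1):n))
  pair_i <- pair_i[keep]; pair_j <- pair_j[keep]

  set.seed(seed)
  perms <- matrix(NA_real_, nrow = n_bins, ncol = n_perm)
  for (p in seq_len(n_perm)) {
    z <- values[sample.int(n)]
    ssq <- rowsum((z[pair_i] - z[pair_j])^2, bin, reorder = TRUE)
    gam <- rep(NA_real_, n_bins)
    gam[as.integer(rownames(ssq))] <- ssq / (2 * np[np > 0])
    perms[, p] <- gam
  }
  lower <- apply(perms, 1, stats::quantile, probs = quantiles[1],
                 na.rm = TRUE, names = FALSE)
  upper <- apply(perms, 1, stats::quantile, probs = quantiles[2],
                 na.rm = TRUE, names = FALSE)
  structure(list(lag = obs$lag, lower = lower, upper = upper,
                 observed = obs, n_perm = n_perm, quantiles = quantiles,
                 seed = seed),
            class = "csr_envelope")
}

#' @export
print.csr_envelope <- function(x, ...) {
  inside <- x$observed$gamma >= x$lower & x$observed$gamma <= x$upper
  cat(sprintf(
    "csr_envelope: %d permutations, %.1f-%.1f%% band, observed inside at %d/%d lags\n",
    x$n_perm, 100 * x$quantiles[1], 100 * x$quantiles[2],
    sum(inside, na.rm = TRUE), sum(!is.na(inside))))
  invisible(x)
}

#' Fraction of lags at which the observed variogram sits inside the envelope
#'
#' @param env A [csr_envelope()].
#' @return Fraction in `[0, 1]` over lags with defined semivariance.
#' @export
envelope_coverage <- function(env) {
  stopifnot(inherits(env, "csr_envelope"))
  g <- env$observed$gamma
  ok <- !is.na(g) & !is.na(env$lower) & !is.na(env$upper)
  mean(g[ok] >= env$lower[ok] & g[ok] <= env$upper[ok])
}
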