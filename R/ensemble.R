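ensemble_methods <- c("IDW", "UK", "GLM", "GAM", "RF", "SV")

#' Inverse-distance-weighted interpolation
#'
#' Prediction at each target is the weighted average of all training values
#' with weights `1 / d^power`; a target coinciding with a training point
#' returns that point's value exactly.
#'
#' @param coords_train,values Training locations (two-column matrix, m) and
#'   values.
#' @param coords_pred Prediction locations.
#' @param power Distance-decay exponent (default 2).
#' @return Numeric vector of predictions.
#' @export
idw_interpolate <- function(coords_train, values, coords_pred, power = 2) {
  coords_train <- as.matrix(coords_train)
  coords_pred <- as.matrix(coords_pred)
  stopifnot(nrow(coords_train) == length(values), power > 0)
  d <- sqrt(outer(coords_pred[, 1], coords_train[, 1], "-")^2 +
            outer(coords_pred[, 2], coords_train[, 2], "-")^2)
  out <- numeric(nrow(coords_pred))
  hit <- d < 1e-9
  exact <- rowSums(hit) > 0
  if (any(exact))
    out[exact] <- values[apply(hit[exact, , drop = FALSE], 1, which.max)]
  if (any(!exact)) {
    w <- 1 / d[!exact, , drop = FALSE]^power
    out[!exact] <- as.vector(w %*% values) / rowSums(w)
  }
  out
}

#' Universal kriging prediction
#'
#' Kriging with a first-order polynomial trend in the projected
#' coordinates. For each prediction point the weights solve the standard
#' semivariance system with unbiasedness constraints for the trend basis
#' `(1, x, y)`; the variogram model is fitted to the OLS residuals of that
#' trend (weighted least squares, best of spherical/exponential) unless one
#' is supplied. With a nugget-free variogram the predictor interpolates the
#' training data exactly.
#'
#' @param coords_train,values Training data.
#' @param coords_pred Prediction locations.
#' @param vgm Optional [fit_variogram_model()] result; fitted from the
#'   trend residuals when `NULL`.
#' @param drift `"linear"` (default, first-order trend) or `"constant"`
#'   (ordinary kriging).
#' @return List with `pred` (predictions) and `vgm` (the variogram model
#'   used).
#' @export
uk_interpolate <- function(coords_train, values, coords_pred, vgm = NULL,
                           drift = c("linear", "constant")) {
  drift <- match.arg(drift)
  coords_train <- as.matrix(coords_train)
  coords_pred <- as.matrix(coords_pred)
  n <- nrow(coords_train)
  stopifnot(n == length(values), n >= if (drift == "linear") 4 else 2)
  Ft <- if (drift == "linear")
    cbind(1, coords_train[, 1], coords_train[, 2]) else
    matrix(1, n, 1)
  Fp <- if (drift == "linear")
    cbind(1, coords_pred[, 1], coords_pred[, 2]) else
    matrix(1, nrow(coords_pred), 1)
  if (is.null(vgm)) {
    res <- stats::lm.fit(Ft, values)$residuals
    vgm <- fit_variogram_model(empirical_variogram(coords_train, res))
  }
  G <- variogram_gamma(as.matrix(stats::dist(coords_train)), vgm$family,
                       vgm$nugget, vgm$psill, vgm$range)
  diag(G) <- 0
  p <- ncol(Ft)
  A <- rbind(cbind(G, Ft), cbind(t(Ft), matrix(0, p, p)))
  d0 <- sqrt(outer(coords_train[, 1], coords_pred[, 1], "-")^2 +
             outer(coords_train[, 2], coords_pred[, 2], "-")^2)
  B <- rbind(variogram_gamma(d0, vgm$family, vgm$nugget, vgm$psill,
                             vgm$range),
             t(Fp))
  W <- tryCatch(solve(A, B), error = function(e) {
    # jitter-and-retry once on a singular system
    A2 <- A
    diag(A2)[seq_len(n)] <- diag(A2)[seq_len(n)] + 1e-8 * max(G)
    tryCatch(solve(A2, B), error = function(e2)
      stop("kriging system is singular even after jitter", call. = FALSE))
  })
  list(pred = as.vector(crossprod(W[seq_len(n), , drop = FALSE], values)),
       vgm = vgm)
}

#' Fit one ensemble member and predict over the grid
#'
#' The six member methods of the interpolation ensemble. IDW and UK work on
#' coordinates only; GLM (linear terms) and GAM (the additive minimal
#' model) use the supplied covariates; RF and SV are seeded regressors (or
#' probability classifiers for presence) on covariates plus coordinates.
#' Presence predictions are probabilities in `[0, 1]`; biomass predictions
#' are clipped at zero.
#'
#' @param method One of `"IDW"`, `"UK"`, `"GLM"`, `"GAM"`, `"RF"`, `"SV"`.
#' @param responses Response table ([build_response_table()]).
#' @param stack A [covariate_stack()].
#' @param response `"biomass"` or `"presence"` (column names in
#'   `responses`).
#' @param covariates Covariate names for GLM/GAM/RF/SV (default: all
#'   layers).
#' @param seed Integer seed (RF/SV).
#' @param idw_power IDW exponent.
#' @param uk_drift Trend for UK.
#' @param k1,k2 GAM basis dimensions.
#' @return An object of class `member_prediction`: list with `method`,
#'   `response`, `insample` (per-plot predictions), `grid` (per-pixel
#'   predictions, column-major), `meta`.
#' @export
fit_predict_member <- function(method, responses, stack,
                               response = c("biomass", "presence"),
                               covariates = NULL, seed = 1,
                               idw_power = 2, uk_drift = "linear",
                               k1 = 9, k2 = 29) {
  response <- match.arg(response)
  if (!method %in% ensemble_methods)
    stop(sprintf("unknown method id '%s'", method), call. = FALSE)
  if (nrow(responses) < 10)
    stop("need at least 10 training plots", call. = FALSE)
  y <- responses[[response]]
  xy <- cbind(responses$Longitude, responses$Latitude)
  grid_tab <- stack_as_table(stack)
  gxy <- cbind(grid_tab$Longitude, grid_tab$Latitude)
  if (is.null(covariates)) covariates <- names(stack$layers)
  is_pres <- response == "presence"
  meta <- list(seed = seed)

  clipfun <- if (is_pres) function(v) pmin(1, pmax(0, v)) else
    function(v) pmax(0, v)

  if (method == "IDW") {
    ins <- idw_interpolate(xy, y, xy, idw_power)
    gr <- idw_interpolate(xy, y, gxy, idw_power)
    meta$power <- idw_power
  } else if (method == "UK") {
    uk <- uk_interpolate(xy, y, gxy, drift = uk_drift)
    ins <- uk_interpolate(xy, y, xy, vgm = uk$vgm, drift = uk_drift)$pred
    gr <- uk$pred
    meta$vgm <- uk$vgm[c("family", "nugget", "psill", "range")]
  } else if (method == "GLM") {
    fml <- stats::as.formula(paste(
      response, "~", paste(c(covariates, "Longitude", "Latitude"),
                           collapse = " + ")))
    fit <- stats::glm(fml, data = responses,
                      family = if (is_pres) stats::binomial() else
                        stats::gaussian())
    ins <- as.vector(stats::predict(fit, type = "response"))
    gr <- as.vector(stats::predict(fit, newdata = grid_tab,
                                   type = "response"))
  } else if (method == "GAM") {
    terms <- c(list(list(vars = c("Longitude", "Latitude"),
                         kind = "smooth2")),
               lapply(covariates, function(v) list(vars = v,
                                                   kind = "smooth1")))
    spec <- model_spec("ensemble GAM", response,
                       if (is_pres) "binomial" else "gaussian", terms)
    fit <- fit_apriori_model(spec, responses, k1, k2)
    ins <- fit$fitted
    gr <- as.vector(stats::predict(fit$gam, newdata = grid_tab,
                                   type = "response"))
  } else if (method == "RF") {
    set.seed(seed)
    xdf <- responses[, c(covariates, "Longitude", "Latitude"), drop = FALSE]
    gdf <- grid_tab[, c(covariates, "Longitude", "Latitude"), drop = FALSE]
    if (is_pres && length(unique(y)) > 1) {
      fit <- randomForest::randomForest(x = xdf, y = factor(y, c(0, 1)),
                                        ntree = 500)
      ins <- stats::predict(fit, xdf, type = "prob")[, "1"]
      gr <- stats::predict(fit, gdf, type = "prob")[, "1"]
    } else {
      fit <- randomForest::randomForest(x = xdf, y = y, ntree = 500)
      ins <- as.vector(stats::predict(fit, xdf))
      gr <- as.vector(stats::predict(fit, gdf))
    }
  } else { # SV
    set.seed(seed)
    xdf <- responses[, c(covariates, "Longitude", "Latitude"), drop = FALSE]
    gdf <- grid_tab[, c(covariates, "Longitude", "Latitude"), drop = FALSE]
    if (is_pres && length(unique(y)) > 1) {
      fit <- e1071::svm(x = xdf, y = factor(y, c(0, 1)),
                        probability = TRUE, kernel = "radial")
      ins <- attr(stats::predict(fit, xdf, probability = TRUE),
                  "probabilities")[, "1"]
      gr <- attr(stats::predict(fit, gdf, probability = TRUE),
                 "probabilities")[, "1"]
    } else {
      fit <- e1071::svm(x = xdf, y = y, kernel = "radial")
      ins <- as.vector(stats::predict(fit, xdf))
      gr <- as.vector(stats::predict(fit, gdf))
    }
  }
  structure(list(method = method, response = response,
                 insample = clipfun(as.vector(ins)),
                 grid = clipfun(as.vector(gr)), meta = meta),
            class = "member_prediction")
}

#' Correlation weights for the ensemble
#'
#' Each member's weight is proportional to the positive part of the
#' Pearson correlation between the observed values and the member's
#' in-sample predictions; members with non-positive correlation get zero
#' weight. Weights are normalised to sum to one.
#'
#' @param members List of [fit_predict_member()] results.
#' @param observed Observed response at the training plots.
#' @return Named numeric vector of weights.
#' @export
ensemble_weights <- function(members, observed) {
  stopifnot(length(members) >= 1)
  r <- vapply(members, function(m) {
    if (stats::sd(m$insample) == 0 || stats::sd(observed) == 0)
      return(0)
    stats::cor(observed, m$insample)
  }, 0)
  names(r) <- vapply(members, `[[`, "", "method")
  w <- pmax(r, 0)
  if (sum(w) == 0)
    stop("no member has positive observed-predicted correlation; ",
         "no valid ensemble", call. = FALSE)
  w / sum(w)
}

#' Combine member grids into the ensemble surface
#'
#' Per-pixel weighted mean; the result is a convex combination, so every
#' ensemble pixel lies within the min/max envelope of the member values.
#'
#' @param members List of `member_prediction` on a common grid.
#' @param weights Weights from [ensemble_weights()] (same order).
#' @return Numeric vector, the ensemble grid (column-major pixel order).
#' @export
ensemble_combine <- function(members, weights) {
  stopifnot(length(members) == length(weights),
            all(weights >= 0), abs(sum(weights) - 1) < 1e-8)
  lens <- vapply(members, function(m) length(m$grid), 0L)
  if (length(unique(lens)) != 1)
    stop("member grids have mismatched dimensions", call. = FALSE)
  g <- matrix(0, nrow = lens[1], ncol = length(members))
  for (i in seq_along(members)) g[, i] <- members[[i]]$grid
  as.vector(g %*% weights)
}

#' Fit the full six-member ensemble for one response
#'
#' @param responses Response table.
#' @param stack A [covariate_stack()].
#' @param response `"biomass"` or `"presence"`.
#' @param members Method ids to include (default all six).
#' @param covariates Covariates for the model-based members.
#' @param seed Seed for RF/SV.
#' @param weight_scheme `"insample"` (default): weights from the
#'   correlation between observations and in-sample predictions;
#'   `"cv"`: k-fold cross-validated predictions (each member refitted
#'   without a fold, held-out plots predicted from the refitted grid).
#' @param folds Number of CV folds when `weight_scheme = "cv"`.
#' @param ... Passed to [fit_predict_member()].
#' @return An object of class `ensemble_result`: `members`, `weights`,
#'   `grid` (ensemble surface), `insample` (ensemble in-sample
#'   predictions), `observed`, `response`.
#' @export
ensemble_interpolate <- function(responses, stack,
                                 response = c("biomass", "presence"),
                                 members = ensemble_methods,
                                 covariates = NULL, seed = 1,
                                 weight_scheme = c("insample", "cv"),
                                 folds = 10, ...) {
  response <- match.arg(response)
  weight_scheme <- match.arg(weight_scheme)
  fits <- lapply(members, fit_predict_member, responses = responses,
                 stack = stack, response = response,
                 covariates = covariates, seed = seed, ...)
  wfits <- fits
  if (weight_scheme == "cv") {
    set.seed(seed)
    n <- nrow(responses)
    fold <- sample(rep_len(seq_len(folds), n))
    rc <- point_to_cell(stack$grid, responses$Longitude,
                        responses$Latitude)
    pix <- (rc$col - 1L) * stack$grid$n_rows + rc$row
    cvpred <- matrix(NA_real_, n, length(members))
    for (f in seq_len(folds)) {
      hold <- fold == f
      sub <- lapply(members, fit_predict_member,
                    responses = responses[!hold, , drop = FALSE],
                    stack = stack, response = response,
                    covariates = covariates, seed = seed, ...)
      for (j in seq_along(sub))
        cvpred[hold, j] <- sub[[j]]$grid[pix[hold]]
    }
    for (j in seq_along(wfits)) wfits[[j]]$insample <- cvpred[, j]
  }
  w <- ensemble_weights(wfits, responses[[response]])
  ins <- sapply(fits, `[[`, "insample") %*% w
  structure(list(members = fits, weights = w,
                 grid = ensemble_combine(fits, w),
                 insample = as.vector(ins),
                 observed = responses[[response]], response = response),
            class = "ensemble_result")
}

#' @export
print.ensemble_result <- function(x, ...) {
  cat(sprintf("ensemble_result [%s]: %d members\n", x$response,
              length(x$members)))
  print(round(x$weights, 3))
  cat(sprintf("  ensemble in-sample cor: %.3f\n",
              stats::cor(x$observed, x$insample)))
  invisible(x)
}

#' Summaries of the interpolated surfaces
#'
#' Occupied fraction/area from the presence surface and the landscape
#' biomass total from the biomass surface:
#' `total Mg = sum(pixel rate kg ha^-1 month^-1 x pixel area ha) / 1000 x
#' n_months`.
#'
#' @param presence_grid Presence-probability pixel vector.
#' @param biomass_grid Biomass-rate pixel vector (kg ha^-1 month^-1).
#' @param grid A [grid_spec()].
#' @param presence_threshold Probability above which a pixel counts as
#'   occupied (default 0.5).
#' @param n_months Number of months the biomass total represents.
#' @return List: `occupied_fraction_pct`, `occupied_km2`,
#'   `total_biomass_Mg`.
#' @export
summarize_prediction_grid <- function(presence_grid, biomass_grid, grid,
                                      presence_threshold = 0.5,
                                      n_months = 1) {
  stopifnot(inherits(grid, "grid_spec"),
            length(presence_grid) == grid$n_rows * grid$n_cols,
            length(biomass_grid) == grid$n_rows * grid$n_cols)
  occ <- mean(presence_grid >= presence_threshold)
  list(
    occupied_fraction_pct = 100 * occ,
    occupied_km2 = occ * grid$total_area_ha / 100,
    total_biomass_Mg = sum(biomass_grid * grid$pixel_area_ha) / 1000 *
      n_months)
}
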