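#' Define an additive model specification
#'
#' @param label Model label (e.g. "Space only", "Full").
#' @param response Response column name in the response table.
#' @param family `"gaussian"` or `"binomial"` (logit link).
#' @param terms List of terms, each `list(vars, kind)` with kind one of
#'   `"smooth1"` (1-d penalized cubic regression spline), `"smooth2"`
#'   (2-d thin-plate spatial smooth, reserved for Longitude/Latitude),
#'   `"linear"`, `"categorical"`.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(label, response, family = c("gaussian", "binomial"),
                       terms) {
  family <- match.arg(family)
  stopifnot(is.list(terms))
  for (tm in terms) {
    stopifnot(!is.null(tm$vars), tm$kind %in%
                c("smooth1", "smooth2", "linear", "categorical"))
    if (tm$kind == "smooth2" && length(tm$vars) != 2)
      stop("smooth2 terms need exactly two variables", call. = FALSE)
  }
  structure(list(label = label, response = response, family = family,
                 terms = terms), class = "model_spec")
}

term_label <- function(tm) {
  if (tm$kind %in% c("smooth1", "smooth2"))
    sprintf("s(%s)", paste(tm$vars, collapse = ","))
  else paste(tm$vars, collapse = ",")
}

term_code <- function(tm, k1, k2) {
  switch(tm$kind,
    smooth1 = sprintf("s(%s, k = %d, bs = \"cr\")", tm$vars, k1),
    smooth2 = sprintf("s(%s, %s, k = %d)", tm$vars[1], tm$vars[2], k2),
    linear = tm$vars,
    categorical = tm$vars)
}

# cap each smooth's basis at what the data can support (mgcv errors when a
# covariate has fewer unique values than knots)
effective_k <- function(tm, table, k1) {
  if (tm$kind != "smooth1") return(k1)
  min(k1, max(3L, length(unique(table[[tm$vars]])) - 1L))
}

#' Model formula of a specification
#'
#' @param spec A [model_spec()].
#' @param k1 Basis dimension for 1-d smooths (default 9).
#' @param k2 Basis dimension for the 2-d spatial smooth (default 29).
#' @param table Optional data; when given, each 1-d smooth's basis is
#'   capped at the number of unique covariate values minus one.
#' @return A formula.
#' @export
spec_formula <- function(spec, k1 = 9, k2 = 29, table = NULL) {
  rhs <- if (length(spec$terms) == 0) "1" else
    paste(vapply(spec$terms, function(tm) term_code(
      tm, if (is.null(table)) k1 else effective_k(tm, table, k1), k2),
      ""), collapse = " + ")
  stats::as.formula(paste(spec$response, "~", rhs),
                    env = globalenv())
}

#' The a-priori model suite
#'
#' The five candidate hypotheses fitted to each response: Space only
#' (2-d spatial smooth + basin), Topography (altitude, slope, aspect),
#' Hydrography (distance to drainage, TWI smooths, SWI linear), Vegetation
#' cover (AGLB and the three EVI layers) and the Full model combining all
#' terms.
#'
#' @param response Response column name.
#' @param family Model family.
#' @return Named list of five [model_spec()] objects.
#' @export
apriori_model_specs <- function(response,
                                family = c("gaussian", "binomial")) {
  family <- match.arg(family)
  s1 <- function(v) list(vars = v, kind = "smooth1")
  sp <- list(
    "Space only" = list(list(vars = c("Longitude", "Latitude"),
                             kind = "smooth2"),
                        list(vars = "Basin", kind = "categorical")),
    "Topography" = lapply(c("Altitude", "Slope", "Aspect"), s1),
    "Hydrography" = c(lapply(c("DND", "TWI"), s1),
                      list(list(vars = "SWI", kind = "linear"))),
    "Vegetation cover" = lapply(c("AGLB", "EVI_diff", "EVI_wet",
                                  "EVI_dry"), s1)
  )
  sp$Full <- c(sp[["Space only"]][1], sp$Topography, sp$Hydrography,
               sp[["Vegetation cover"]], sp[["Space only"]][2])
  lapply(sp, function(tm) model_spec(
    label = "", response = response, family = family, terms = tm))
}

n_model_vars <- function(spec) {
  length(unique(unlist(lapply(spec$terms, `[[`, "vars"))))
}

#' Screen candidate covariates for collinearity
#'
#' For every pair of numeric candidates with `|Pearson r| >= threshold`,
#' drops the member with the weaker absolute univariate correlation to the
#' response. Pairs are visited in decreasing `|r|` order so the rule is
#' deterministic. Constant columns are dropped with a warning.
#'
#' @param table Response table.
#' @param vars Candidate numeric variable names.
#' @param response Response column used for the keep/drop decision.
#' @param threshold Absolute-correlation cutoff (default 0.7).
#' @return List with `retained`, `dropped`, `cor_matrix` and `report`
#'   (data.frame of all pairwise correlations).
#' @export
collinearity_screen <- function(table, vars, response, threshold = 0.7) {
  stopifnot(length(vars) >= 2, all(vars %in% names(table)),
            response %in% names(table))
  const <- vars[vapply(vars, function(v) stats::sd(table[[v]]) == 0,
                       TRUE)]
  if (length(const)) {
    warning(sprintf("dropping constant column(s): %s",
                    paste(const, collapse = ", ")), call. = FALSE)
    vars <- setdiff(vars, const)
  }
  cm <- stats::cor(table[, vars, drop = FALSE])
  ry <- vapply(vars, function(v) abs(stats::cor(table[[v]],
                                                table[[response]])), 0)
  pairs <- which(upper.tri(cm), arr.ind = TRUE)
  report <- data.frame(var1 = vars[pairs[, 1]], var2 = vars[pairs[, 2]],
                       r = cm[pairs])
  report <- report[order(-abs(report$r)), , drop = FALSE]
  rownames(report) <- NULL
  dropped <- character()
  for (i in seq_len(nrow(report))) {
    v1 <- report$var1[i]; v2 <- report$var2[i]
    if (v1 %in% dropped || v2 %in% dropped) next
    if (abs(report$r[i]) >= threshold)
      dropped <- c(dropped, if (ry[v1] >= ry[v2]) v2 else v1)
  }
  list(retained = setdiff(vars, dropped), dropped = c(const, dropped),
       cor_matrix = cm, report = report)
}

#' Fit one penalized-spline additive model
#'
#' Fits the specification with `mgcv::gam`, penalized cubic regression
#' splines for 1-d smooths, a thin-plate smooth for the 2-d spatial term,
#' and smoothing parameters selected by maximum likelihood
#' (`method = "ML"`). Metrics: deviance explained
#' `DE% = 100 (null dev - residual dev) / null dev`, AIC and BIC on the
#' penalized fit's effective degrees of freedom, RMSE and Pearson
#' correlation between observed and fitted values (response scale).
#'
#' @param spec A [model_spec()].
#' @param table Response table (must contain all variables).
#' @param k1,k2 Basis dimensions (see [spec_formula()]).
#' @return An object of class `model_fit`: list with `spec`, `gam` (the
#'   mgcv fit), `fitted`, `metrics` (`de_pct`, `aic`, `bic`, `rmse`,
#'   `cor`), `edf` and `term_pvalues` (named per term label).
#' @export
fit_apriori_model <- function(spec, table, k1 = 9, k2 = 29) {
  stopifnot(inherits(spec, "model_spec"))
  vars <- unique(unlist(lapply(spec$terms, `[[`, "vars")))
  miss <- setdiff(c(spec$response, vars), names(table))
  if (length(miss))
    stop(sprintf("missing columns: %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  fam <- if (spec$family == "binomial") stats::binomial() else
    stats::gaussian()
  fit <- mgcv::gam(spec_formula(spec, k1, k2, table), family = fam,
                   data = table, method = "ML")
  mu <- as.vector(stats::fitted(fit))
  y <- table[[spec$response]]
  sm <- summary(fit)
  de <- 100 * sm$dev.expl
  r <- if (stats::sd(mu) == 0 || stats::sd(y) == 0) 0 else
    stats::cor(y, mu)
  pv <- numeric(0)
  if (!is.null(sm$s.table) && nrow(sm$s.table) > 0) {
    ps <- sm$s.table[, "p-value"]
    names(ps) <- rownames(sm$s.table)
    # strip basis-size suffix: "s(Slope)" stays "s(Slope)"
    pv <- c(pv, ps)
  }
  if (!is.null(sm$pTerms.table) && nrow(sm$pTerms.table) > 0) {
    pp <- sm$pTerms.table[, "p-value"]
    names(pp) <- rownames(sm$pTerms.table)
    pv <- c(pv, pp)
  }
  # map mgcv labels back to our term labels
  term_p <- vapply(spec$terms, function(tm) {
    lbl <- term_label(tm)
    key <- if (tm$kind == "smooth2")
      sprintf("s(%s,%s)", tm$vars[1], tm$vars[2]) else lbl
    if (key %in% names(pv)) pv[[key]] else NA_real_
  }, 0)
  names(term_p) <- vapply(spec$terms, term_label, "")
  structure(list(
    spec = spec, gam = fit, fitted = mu,
    metrics = list(
      de_pct = de, aic = stats::AIC(fit), bic = stats::BIC(fit),
      rmse = sqrt(mean((y - mu)^2)), cor = r),
    edf = sum(fit$edf), term_pvalues = term_p),
    class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("model_fit [%s, %s]: DE %.1f%%, AIC %.1f, BIC %.1f, RMSE %.3g, cor %.2f\n",
              x$spec$response, x$spec$family, m$de_pct, m$aic, m$bic,
              m$rmse, m$cor))
  cat("  terms:", paste(names(x$term_pvalues), collapse = " + "), "\n")
  invisible(x)
}

#' Compare the a-priori model suite
#'
#' Fits each specification to the same data and tabulates the metrics,
#' ranked by AIC. With `screen = TRUE` (default) each model's numeric
#' covariates are first screened for collinearity within the model and
#' offending terms removed. A model that fails to fit is reported with NA
#' metrics rather than aborting the set.
#'
#' @param specs Named list of [model_spec()] (e.g.
#'   [apriori_model_specs()]).
#' @param table Response table.
#' @param screen Apply [collinearity_screen()] within each model.
#' @param threshold Collinearity cutoff.
#' @param k1,k2 Basis dimensions.
#' @return List with `table` (data.frame: `model`, `n_vars`, `de_pct`,
#'   `aic`, `bic`, `rmse`, `cor`, sorted by AIC) and `fits` (named list of
#'   `model_fit`, in input order).
#' @export
compare_models <- function(specs, table, screen = TRUE, threshold = 0.7,
                           k1 = 9, k2 = 29) {
  stopifnot(is.list(specs), length(specs) >= 1)
  fits <- vector("list", length(specs))
  names(fits) <- names(specs)
  rows <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    spec <- specs[[i]]
    if (screen) {
      num <- vapply(spec$terms, function(tm)
        tm$kind %in% c("smooth1", "linear") && length(tm$vars) == 1, TRUE)
      numvars <- unlist(lapply(spec$terms[num], `[[`, "vars"))
      if (length(numvars) >= 2) {
        scr <- collinearity_screen(table, numvars, spec$response,
                                   threshold)
        keep <- vapply(spec$terms, function(tm)
          !(term_label(tm) %in% vapply(
            spec$terms[num][numvars %in% scr$dropped], term_label, "")),
          TRUE)
        spec$terms <- spec$terms[keep]
      }
    }
    fit <- tryCatch(fit_apriori_model(spec, table, k1, k2),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      warning(sprintf("model '%s' failed: %s", names(specs)[i],
                      conditionMessage(fit)), call. = FALSE)
      rows[[i]] <- data.frame(model = names(specs)[i],
                              n_vars = n_model_vars(spec), de_pct = NA,
                              aic = NA, bic = NA, rmse = NA, cor = NA)
    } else {
      fits[[i]] <- fit
      m <- fit$metrics
      rows[[i]] <- data.frame(model = names(specs)[i],
                              n_vars = n_model_vars(spec),
                              de_pct = m$de_pct, aic = m$aic, bic = m$bic,
                              rmse = m$rmse, cor = m$cor)
    }
  }
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$aic), , drop = FALSE]
  rownames(tab) <- NULL
  list(table = tab, fits = fits)
}

#' Backward stepwise selection of the minimal model
#'
#' Starting from the full specification (after optional collinearity
#' screening), repeatedly removes the non-significant term (approximate
#' p >= `alpha`) with the largest p-value, provided the refitted model's
#' AIC does not increase by more than `aic_tol`; ties on p are broken by
#' the larger AIC improvement, then alphabetically by term label. Stops
#' when every remaining term is significant or no removal is admissible.
#'
#' @param spec Full-model [model_spec()].
#' @param table Response table.
#' @param alpha Significance level to retain a term (default 0.05).
#' @param aic_tol Maximum tolerated AIC increase on removal (default 2).
#' @param screen,threshold Collinearity screening as in
#'   [compare_models()].
#' @param k1,k2 Basis dimensions.
#' @return List with `fit` (the minimal `model_fit`; an empty
#'   intercept-only model is valid and flagged via `empty = TRUE`) and
#'   `trail` (data.frame of removals: `step`, `term`, `p_value`,
#'   `aic_before`, `aic_after`).
#' @export
backward_select_minimal <- function(spec, table, alpha = 0.05, aic_tol = 2,
                                    screen = TRUE, threshold = 0.7,
                                    k1 = 9, k2 = 29) {
  stopifnot(inherits(spec, "model_spec"), alpha > 0, alpha < 1)
  if (screen) {
    num <- vapply(spec$terms, function(tm)
      tm$kind %in% c("smooth1", "linear") && length(tm$vars) == 1, TRUE)
    numvars <- unlist(lapply(spec$terms[num], `[[`, "vars"))
    if (length(numvars) >= 2) {
      scr <- collinearity_screen(table, numvars, spec$response, threshold)
      spec$terms <- spec$terms[vapply(spec$terms, function(tm)
        !(tm$kind %in% c("smooth1", "linear") &&
            all(tm$vars %in% scr$dropped)), TRUE)]
    }
  }
  cur <- spec
  fit <- fit_apriori_model(cur, table, k1, k2)
  trail <- list()
  step <- 0L
  repeat {
    pv <- fit$term_pvalues
    cand <- which(!is.na(pv) & pv >= alpha)
    if (length(cand) == 0) break
    # largest p first; evaluate AIC for ties to break by improvement
    pmax_ <- max(pv[cand])
    tied <- cand[abs(pv[cand] - pmax_) < 1e-12]
    tried <- lapply(sort(names(pv)[tied]), function(lbl) {
      idx <- which(vapply(cur$terms, term_label, "") == lbl)
      new_spec <- cur
      new_spec$terms <- new_spec$terms[-idx]
      nf <- tryCatch(fit_apriori_model(new_spec, table, k1, k2),
                     error = function(e) NULL)
      list(label = lbl, spec = new_spec, fit = nf,
           aic = if (is.null(nf)) Inf else nf$metrics$aic)
    })
    aics <- vapply(tried, `[[`, 0, "aic")
    best <- tried[[which.min(aics)]]
    if (best$aic > fit$metrics$aic + aic_tol) {
      # the worst term resists removal; try the remaining candidates once
      others <- cand[!(cand %in% tied)]
      if (length(others) == 0) break
      accepted <- FALSE
      for (lbl in names(sort(pv[others], decreasing = TRUE))) {
        idx <- which(vapply(cur$terms, term_label, "") == lbl)
        new_spec <- cur
        new_spec$terms <- new_spec$terms[-idx]
        nf <- tryCatch(fit_apriori_model(new_spec, table, k1, k2),
                       error = function(e) NULL)
        if (!is.null(nf) && nf$metrics$aic <= fit$metrics$aic + aic_tol) {
          best <- list(label = lbl, spec = new_spec, fit = nf,
                       aic = nf$metrics$aic)
          accepted <- TRUE
          break
        }
      }
      if (!accepted) break
    }
    step <- step + 1L
    trail[[step]] <- data.frame(step = step, term = best$label,
                                p_value = pv[[best$label]],
                                aic_before = fit$metrics$aic,
                                aic_after = best$aic)
    cur <- best$spec
    fit <- best$fit
    if (length(cur$terms) == 0) break
  }
  trail <- if (length(trail)) do.call(rbind, trail) else
    data.frame(step = integer(), term = character(), p_value = numeric(),
               aic_before = numeric(), aic_after = numeric())
  rownames(trail) <- NULL
  list(fit = fit, trail = trail, empty = length(cur$terms) == 0)
}
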