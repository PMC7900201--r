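test_that("collinearity screen drops the weaker of a correlated pair", {
  set.seed(1)
  n <- 100
  d <- data.frame(a = rnorm(n))
  d$b <- d$a                      # exact duplicate
  d$c <- rnorm(n)
  d$y <- d$a + rnorm(n, 0, 0.2)
  scr <- collinearity_screen(d, c("a", "b", "c"), "y", threshold = 0.7)
  expect_length(intersect(c("a", "b"), scr$retained), 1)
  expect_true("c" %in% scr$retained)
  # independent columns all retained
  d2 <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n),
                   y = rnorm(n))
  scr2 <- collinearity_screen(d2, c("a", "b", "c"), "y")
  expect_setequal(scr2$retained, c("a", "b", "c"))
  # constant column flagged and dropped
  d2$k <- 1
  expect_warning(scr3 <- collinearity_screen(d2, c("a", "b", "k"), "y"),
                 "constant")
  expect_false("k" %in% scr3$retained)
})

test_that("collinearity screen equals an exhaustive pair-scan oracle", {
  # known correlation structure among four variables
  set.seed(2)
  n <- 300
  z <- rnorm(n)
  d <- data.frame(v1 = z + rnorm(n, 0, 0.3),       # v1 ~ v2 strongly
                  v2 = z + rnorm(n, 0, 0.3),
                  v3 = rnorm(n),
                  v4 = rnorm(n))
  d$y <- d$v1 + 0.5 * d$v3 + rnorm(n, 0, 0.5)
  thr <- 0.7
  scr <- collinearity_screen(d, paste0("v", 1:4), "y", thr)
  # oracle: visit pairs by decreasing |r|, drop weaker-to-response member
  vars <- paste0("v", 1:4)
  cm <- cor(d[vars])
  ry <- sapply(vars, function(v) abs(cor(d[[v]], d$y)))
  prs <- which(upper.tri(cm), arr.ind = TRUE)
  ord <- order(-abs(cm[prs]))
  dropped <- character()
  for (k in ord) {
    v1 <- vars[prs[k, 1]]; v2 <- vars[prs[k, 2]]
    if (v1 %in% dropped || v2 %in% dropped) next
    if (abs(cm[prs[k, 1], prs[k, 2]]) >= thr)
      dropped <- c(dropped, if (ry[v1] >= ry[v2]) v2 else v1)
  }
  expect_setequal(scr$retained, setdiff(vars, dropped))
})

test_that("additive model fits saturate on noise-free linear data", {
  d <- linear_fixture(noise = 0)
  spec <- model_spec("lin", "y", "gaussian",
                     list(list(vars = "x1", kind = "linear"),
                          list(vars = "x2", kind = "linear")))
  # mgcv's ML step warns when the residual variance hits zero; expected
  # in this saturating case
  fit <- suppressWarnings(fit_apriori_model(spec, d))
  expect_equal(fit$metrics$de_pct, 100, tolerance = 1e-6)
  expect_lt(fit$metrics$rmse, 1e-8)
  expect_equal(fit$metrics$cor, 1, tolerance = 1e-8)
})

test_that("intercept-only model explains nothing and fits the mean", {
  d <- linear_fixture(noise = 0.5)
  spec <- model_spec("null", "y", "gaussian", list())
  fit <- fit_apriori_model(spec, d)
  expect_equal(fit$metrics$de_pct, 0, tolerance = 1e-10)
  expect_equal(unique(round(fit$fitted, 10)), round(mean(d$y), 10))
})

test_that("gaussian AIC/BIC match the closed-form least-squares oracle", {
  d <- linear_fixture(noise = 0.4)
  spec <- model_spec("lin", "y", "gaussian",
                     list(list(vars = "x1", kind = "linear"),
                          list(vars = "x2", kind = "linear"),
                          list(vars = "x3", kind = "linear")))
  fit <- fit_apriori_model(spec, d)
  # closed form: ML gaussian log-likelihood of OLS with p+1 parameters +
  # the variance parameter
  X <- cbind(1, d$x1, d$x2, d$x3)
  n <- nrow(d)
  beta <- solve(crossprod(X), crossprod(X, d$y))
  rss <- sum((d$y - X %*% beta)^2)
  ll <- -n / 2 * (log(2 * pi) + log(rss / n) + 1)
  k <- ncol(X) + 1
  expect_equal(fit$metrics$aic, -2 * ll + 2 * k, tolerance = 1e-6)
  expect_equal(fit$metrics$bic, -2 * ll + log(n) * k, tolerance = 1e-6)
})

test_that("deviance explained equals 100 R^2 for gaussian fits", {
  r <- default_responses()
  spec <- model_spec("m", "biomass", "gaussian",
                     list(list(vars = "Altitude", kind = "smooth1"),
                          list(vars = "DND", kind = "smooth1")))
  fit <- fit_apriori_model(spec, r)
  r2 <- 1 - sum((r$biomass - fit$fitted)^2) /
    sum((r$biomass - mean(r$biomass))^2)
  expect_equal(fit$metrics$de_pct, 100 * r2, tolerance = 1e-8)
  expect_gte(fit$metrics$de_pct, 0)
  expect_lte(fit$metrics$de_pct, 100)
  # RMSE of a non-degenerate fit stays below the response SD
  expect_lt(fit$metrics$rmse, sd(r$biomass))
})

test_that("binomial fits return probabilities and their RMSE", {
  r <- default_responses()
  spec <- model_spec("m", "presence", "binomial",
                     list(list(vars = c("Longitude", "Latitude"),
                               kind = "smooth2")))
  fit <- fit_apriori_model(spec, r)
  expect_true(all(fit$fitted > 0 & fit$fitted < 1))
  expect_equal(fit$metrics$rmse,
               sqrt(mean((r$presence - fit$fitted)^2)))
})

test_that("five a-priori specs produce five ranked metric rows", {
  r <- default_responses()
  specs <- apriori_model_specs("biomass", "gaussian")
  expect_length(specs, 5)
  cmp <- compare_models(specs, r)
  expect_equal(nrow(cmp$table), 5)
  expect_setequal(cmp$table$model,
                  c("Space only", "Topography", "Hydrography",
                    "Vegetation cover", "Full"))
  expect_true(all(c("de_pct", "aic", "bic", "rmse", "cor") %in%
                    names(cmp$table)))
  expect_true(!is.unsorted(cmp$table$aic))
  # identical specs give identical rows
  cmp2 <- compare_models(list(a = specs[[2]], b = specs[[2]]), r)
  expect_equal(cmp2$table$aic[1], cmp2$table$aic[2])
  expect_equal(cmp2$table$de_pct[1], cmp2$table$de_pct[2])
})

test_that("spatial signal puts the space-only model first", {
  wins <- vapply(1:15, function(s) {
    cfg <- sim_config(seed = 7000 + s,
                      biomass = list(intercept = log(40), effects = c(),
                                     grf = list(psill = 1, range = 600,
                                                nugget = 0),
                                     sigma_obs = 0.3))
    grid <- grid_spec()
    stack <- generate_covariate_stack(cfg, grid)
    surf <- simulate_fruitfall_surface(stack, cfg)
    des <- sample_survey_design(grid, cfg)
    rc <- point_to_cell(grid, des$plots$x, des$plots$y)
    cov <- extract_at_points(stack, des$plots$x, des$plots$y)
    set.seed(cfg$seed + 5)
    tab <- cbind(
      data.frame(biomass = log(surf$cond_biomass[cbind(rc$row, rc$col)]) +
                   rnorm(90, 0, 0.3),
                 Longitude = des$plots$x, Latitude = des$plots$y), cov)
    specs <- apriori_model_specs("biomass", "gaussian")
    cmp <- compare_models(specs[c("Space only", "Topography",
                                  "Hydrography", "Vegetation cover")],
                          tab)
    cmp$table$model[1] == "Space only"
  }, TRUE)
  expect_gte(mean(wins), 0.8)
})

test_that("backward selection drops noise terms and keeps informative ones", {
  res <- vapply(1:20, function(s) {
    set.seed(s)
    n <- 90
    tab <- data.frame(x_info = runif(n), x_noise = runif(n))
    tab$y <- sin(2 * pi * tab$x_info) + rnorm(n, 0, 0.4)
    spec <- model_spec("full", "y", "gaussian",
                       list(list(vars = "x_info", kind = "smooth1"),
                            list(vars = "x_noise", kind = "smooth1")))
    sel <- backward_select_minimal(spec, tab, screen = FALSE)
    kept <- names(sel$fit$term_pvalues)
    c("s(x_info)" %in% kept, !("s(x_noise)" %in% kept),
      sel$fit$metrics$aic <= fit_apriori_model(spec, tab)$metrics$aic + 2)
  }, logical(3))
  expect_gte(mean(res[1, ]), 0.9)   # informative retained
  expect_gte(mean(res[2, ]), 0.9)   # noise dropped
  expect_true(all(res[3, ]))        # AIC never worse than full + 2
})

test_that("strongly informative terms survive selection; empty models are
           flagged", {
  d <- linear_fixture(n = 120, noise = 0.1)
  spec <- model_spec("full", "y", "gaussian",
                     list(list(vars = "x1", kind = "smooth1"),
                          list(vars = "x2", kind = "smooth1")))
  sel <- backward_select_minimal(spec, d, screen = FALSE)
  expect_setequal(names(sel$fit$term_pvalues), c("s(x1)", "s(x2)"))
  expect_equal(nrow(sel$trail), 0)
  expect_false(sel$empty)
  # pure noise response: everything may go, flagged as empty
  set.seed(50)
  d2 <- data.frame(x1 = runif(60), x2 = runif(60), y = rnorm(60))
  sel2 <- backward_select_minimal(
    model_spec("full", "y", "gaussian",
               list(list(vars = "x1", kind = "smooth1"),
                    list(vars = "x2", kind = "smooth1"))),
    d2, screen = FALSE)
  expect_true(sel2$empty || length(sel2$fit$term_pvalues) < 2)
})
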