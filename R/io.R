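# Polynomial rolling hash of the serialized object; stamps outputs with the
# configuration identity (not cryptographic).
config_hash <- function(obj) {
  s <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, force = TRUE)
  h <- 5381
  for (b in utf8ToInt(as.character(s)))
    h <- (h * 31 + b) %% 4294967296
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}

write_asc <- function(m, grid, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", grid$n_cols),
    sprintf("nrows %d", grid$n_rows),
    sprintf("xllcorner %.10g", grid$origin_x),
    sprintf("yllcorner %.10g", grid$origin_y),
    sprintf("cellsize %.10g", grid$cell_size),
    "NODATA_value -9999"), con)
  # ASCII grids store the top (northern) row first; row 1 is southern here
  for (r in rev(seq_len(nrow(m))))
    writeLines(paste(sprintf("%.17g", m[r, ]), collapse = " "), con)
}

read_asc <- function(path) {
  hdr <- utils::read.table(path, nrows = 6,
                           col.names = c("key", "value"),
                           colClasses = c("character", "numeric"))
  vals <- as.matrix(utils::read.table(path, skip = 6))
  g <- stats::setNames(hdr$value, tolower(hdr$key))
  m <- matrix(NA_real_, nrow = g[["nrows"]], ncol = g[["ncols"]])
  for (i in seq_len(g[["nrows"]]))
    m[g[["nrows"]] - i + 1, ] <- vals[i, ]
  list(matrix = m,
       grid = grid_spec(g[["xllcorner"]], g[["yllcorner"]],
                        g[["nrows"]], g[["ncols"]], g[["cellsize"]]))
}

#' Write a covariate stack to disk
#'
#' One ESRI ASCII grid (`.asc`) per layer plus `Basin.asc`, with a
#' `stack.json` sidecar recording the band names, grid and a content hash.
#' Values are written at full double precision so a round trip is
#' bit-exact.
#'
#' @param stack A [covariate_stack()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_covariate_stack <- function(stack, dir) {
  stopifnot(inherits(stack, "covariate_stack"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(stack$layers))
    write_asc(stack$layers[[nm]], stack$grid,
              file.path(dir, paste0(nm, ".asc")))
  write_asc(stack$basin, stack$grid, file.path(dir, "Basin.asc"))
  meta <- list(bands = names(stack$layers), basin_band = "Basin",
               grid = unclass(stack$grid),
               hash = config_hash(lapply(stack$layers, dim)))
  jsonlite::write_json(meta, file.path(dir, "stack.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a covariate stack written by [write_covariate_stack()]
#'
#' @param dir Directory containing the `.asc` bands and `stack.json`.
#' @return A [covariate_stack()].
#' @export
read_covariate_stack <- function(dir) {
  meta_path <- file.path(dir, "stack.json")
  if (!file.exists(meta_path))
    stop(sprintf("no stack.json in '%s'", dir), call. = FALSE)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  layers <- list()
  grid <- NULL
  for (nm in meta$bands) {
    p <- file.path(dir, paste0(nm, ".asc"))
    if (!file.exists(p))
      stop(sprintf("missing band '%s' (%s)", nm, basename(p)),
           call. = FALSE)
    r <- read_asc(p)
    if (is.null(grid)) grid <- r$grid
    else if (!isTRUE(all.equal(unclass(grid), unclass(r$grid))))
      stop(sprintf("band '%s' grid does not match the stack grid", nm),
           call. = FALSE)
    layers[[nm]] <- r$matrix
  }
  b <- read_asc(file.path(dir, "Basin.asc"))
  covariate_stack(grid, layers, b$matrix)
}

#' Read and validate the survey tables
#'
#' @param observations_path CSV with columns `plot_id`, `species`,
#'   `status`, `count` (optionally `survey_month`, `removable`).
#' @param species_mass_path CSV with columns `species`,
#'   `mean_dry_mass_g`, `n_weighed` (optionally `removable`).
#' @param plots_path Optional CSV with `plot_id`, `x`, `y`, `area_m2`.
#' @return List `observations`, `species_mass` and (if given) `plots`.
#'   Unknown status codes, negative counts, nonpositive masses and
#'   duplicate plot or species ids raise errors naming the offender.
#' @export
read_plot_tables <- function(observations_path, species_mass_path,
                             plots_path = NULL) {
  obs <- utils::read.csv(observations_path, stringsAsFactors = FALSE)
  need <- c("plot_id", "species", "status", "count")
  miss <- setdiff(need, names(obs))
  if (length(miss))
    stop(sprintf("observations file lacks column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  bad <- which(!obs$status %in% valid_statuses)
  if (length(bad))
    stop(sprintf("unknown status code '%s' at observation row %d",
                 obs$status[bad[1]], bad[1]), call. = FALSE)
  neg <- which(obs$count < 0)
  if (length(neg))
    stop(sprintf("negative count at observation row %d", neg[1]),
         call. = FALSE)
  sm <- utils::read.csv(species_mass_path, stringsAsFactors = FALSE)
  if (!all(c("species", "mean_dry_mass_g") %in% names(sm)))
    stop("species mass file lacks species/mean_dry_mass_g columns",
         call. = FALSE)
  if (anyDuplicated(sm$species))
    stop(sprintf("duplicate species in mass table: %s",
                 sm$species[duplicated(sm$species)][1]), call. = FALSE)
  if (any(sm$mean_dry_mass_g <= 0))
    stop("mean dry mass must be positive", call. = FALSE)
  out <- list(observations = obs, species_mass = sm)
  if (!is.null(plots_path)) {
    pl <- utils::read.csv(plots_path, stringsAsFactors = FALSE)
    if (anyDuplicated(pl$plot_id))
      stop(sprintf("duplicate plot id: %s",
                   pl$plot_id[duplicated(pl$plot_id)][1]), call. = FALSE)
    if (any(pl$area_m2 <= 0))
      stop("plot areas must be positive", call. = FALSE)
    out$plots <- pl
  }
  out
}

#' Pipeline configuration
#'
#' @param seed Master seed; all stages derive their randomness from it.
#' @param out_dir Output directory for all artifacts.
#' @param grid A [grid_spec()].
#' @param sim A [sim_config()] (its seed is overridden by `seed`).
#' @param variogram Options: `n_bins`, `max_lag`, `n_perm`, `quantiles`.
#' @param models Options: `alpha`, `aic_tol`, `threshold`, `k1`, `k2`.
#' @param ensemble Options: `members`, `idw_power`, `uk_drift`,
#'   `presence_threshold`.
#' @param accounting Constants: `agb_per_ha_mean` (Mg ha^-1),
#'   `fruits_per_tree`.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 42L, out_dir = tempfile("fruitfall-"),
                            grid = grid_spec(), sim = sim_config(),
                            variogram = list(n_bins = 15, max_lag = NULL,
                                             n_perm = 999,
                                             quantiles = c(0.025, 0.975)),
                            models = list(alpha = 0.05, aic_tol = 2,
                                          threshold = 0.7, k1 = 9,
                                          k2 = 29),
                            ensemble = list(members = ensemble_methods,
                                            idw_power = 2,
                                            uk_drift = "linear",
                                            presence_threshold = 0.5),
                            accounting = list(agb_per_ha_mean = 423.8,
                                              fruits_per_tree = 4000)) {
  sim$seed <- as.integer(seed)
  structure(list(seed = as.integer(seed), out_dir = out_dir, grid = grid,
                 sim = sim, variogram = variogram, models = models,
                 ensemble = ensemble, accounting = accounting),
            class = "pipeline_config")
}

stage_log <- function(stage, t0, ...) {
  message(sprintf("[%s] %5.1fs %s", stage,
                  as.numeric(Sys.time()) - t0,
                  paste(sprintf("%s=%s", names(list(...)),
                                unlist(list(...))), collapse = " ")))
}

#' Run the full analysis pipeline
#'
#' simulate -> responses -> variograms + CSR envelopes -> a-priori model
#' comparison and minimal models -> six-member ensemble interpolation for
#' presence and biomass -> landscape summaries -> up-scaling account.
#' Every artifact is written under `config$out_dir` and stamped with the
#' configuration hash; a fixed seed makes the whole run byte-reproducible.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with all in-memory stage results
#'   (`responses`, `variograms`, `model_comparison`, `minimal`,
#'   `ensembles`, `summary`, `accounting`, `out_dir`).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- as.numeric(Sys.time())
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(unclass(config)[c("seed", "variogram", "models",
                                        "ensemble", "accounting")])

  land <- simulate_landscape(config$sim, config$grid)
  write_covariate_stack(land$stack, file.path(out, "covariates"))
  utils::write.csv(land$design$plots, file.path(out, "plots.csv"),
                   row.names = FALSE)
  utils::write.csv(land$observations, file.path(out, "observations.csv"),
                   row.names = FALSE)
  utils::write.csv(land$species_mass, file.path(out, "species_mass.csv"),
                   row.names = FALSE)
  stage_log("simulate", t0, seed = config$seed,
            plots = nrow(land$design$plots), hash = hash)

  responses <- build_response_table(
    land$observations, land$design$plots, land$species_mass, land$stack,
    focal_species = config$sim$dominant_species,
    n_survey_months = config$sim$n_survey_months)
  utils::write.csv(responses, file.path(out, "responses.csv"),
                   row.names = FALSE)
  stage_log("responses", t0, rows = nrow(responses),
            present = sum(responses$presence))

  xy <- cbind(responses$Longitude, responses$Latitude)
  vg <- list()
  for (resp in c("biomass", "presence")) {
    v <- responses[[resp]]
    env <- csr_envelope(xy, v, n_perm = config$variogram$n_perm,
                        quantiles = config$variogram$quantiles,
                        seed = config$seed,
                        n_bins = config$variogram$n_bins,
                        max_lag = config$variogram$max_lag)
    fit <- fit_variogram_model(env$observed)
    vg[[resp]] <- list(envelope = env, model = fit)
    utils::write.csv(
      data.frame(lag = env$lag, gamma = env$observed$gamma,
                 n_pairs = env$observed$n_pairs, lower = env$lower,
                 upper = env$upper),
      file.path(out, sprintf("variogram_%s.csv", resp)),
      row.names = FALSE)
  }
  jsonlite::write_json(
    lapply(vg, function(v) c(v$model[c("family", "nugget", "psill",
                                       "range", "sill")],
                             nugget_sill_ratio = nugget_sill_ratio(v$model),
                             config_hash = hash)),
    file.path(out, "variogram_models.json"), auto_unbox = TRUE,
    digits = NA)
  stage_log("variogram", t0, n_perm = config$variogram$n_perm)

  mo <- config$models
  comparison <- list(); minimal <- list()
  for (resp in c("biomass", "presence")) {
    fam <- if (resp == "presence") "binomial" else "gaussian"
    specs <- apriori_model_specs(resp, fam)
    cmp <- compare_models(specs, responses, threshold = mo$threshold,
                          k1 = mo$k1, k2 = mo$k2)
    sel <- backward_select_minimal(specs$Full, responses,
                                   alpha = mo$alpha, aic_tol = mo$aic_tol,
                                   threshold = mo$threshold, k1 = mo$k1,
                                   k2 = mo$k2)
    comparison[[resp]] <- cmp
    minimal[[resp]] <- sel
    cmp$table$response <- resp
    utils::write.csv(cmp$table,
                     file.path(out, sprintf("model_comparison_%s.csv",
                                            resp)),
                     row.names = FALSE)
  }
  jsonlite::write_json(
    lapply(minimal, function(sel) list(
      terms = names(sel$fit$term_pvalues),
      metrics = sel$fit$metrics, removed = sel$trail$term,
      empty = sel$empty, config_hash = hash)),
    file.path(out, "minimal_models.json"), auto_unbox = TRUE, digits = NA)
  stage_log("models", t0,
            minimal_biomass = length(minimal$biomass$fit$term_pvalues),
            minimal_presence = length(minimal$presence$fit$term_pvalues))

  en <- config$ensemble
  minvars <- function(sel) {
    v <- setdiff(unique(unlist(lapply(sel$fit$spec$terms, `[[`, "vars"))),
                 c("Longitude", "Latitude", "Basin"))
    if (length(v) == 0) NULL else v
  }
  ensembles <- list()
  for (resp in c("biomass", "presence")) {
    ensembles[[resp]] <- ensemble_interpolate(
      responses, land$stack, response = resp, members = en$members,
      covariates = minvars(minimal[[resp]]), seed = config$seed,
      idw_power = en$idw_power, uk_drift = en$uk_drift,
      k1 = mo$k1, k2 = mo$k2)
    write_asc(matrix(ensembles[[resp]]$grid, config$grid$n_rows,
                     config$grid$n_cols),
              config$grid,
              file.path(out, sprintf("ensemble_%s.asc", resp)))
  }
  jsonlite::write_json(
    lapply(ensembles, function(e) as.list(e$weights)),
    file.path(out, "weights.json"), auto_unbox = TRUE, digits = NA)
  stage_log("ensemble", t0, members = length(en$members))

  summ <- summarize_prediction_grid(
    ensembles$presence$grid, ensembles$biomass$grid, config$grid,
    presence_threshold = en$presence_threshold,
    n_months = config$sim$n_survey_months)
  summ$config_hash <- hash
  jsonlite::write_json(summ, file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = NA)

  acct <- upscaling_account(
    mean_monthly = mean(responses$biomass_overall_monthly),
    area_ha = config$grid$total_area_ha,
    masting_total_Mg = summ$total_biomass_Mg,
    agb_min_Mg = sum(land$stack$layers$AGLB * config$grid$pixel_area_ha),
    agb_max_Mg = config$accounting$agb_per_ha_mean *
      config$grid$total_area_ha,
    fruits_per_tree = config$accounting$fruits_per_tree,
    fruit_mass_g = config$sim$dominant_mass_g,
    seed_mass_g = config$sim$dominant_seed_mass_g,
    max_plot_monthly = max(responses$biomass_monthly),
    n_event_months = config$sim$n_survey_months)
  acct_out <- unclass(acct)
  acct_out$config_hash <- hash
  jsonlite::write_json(acct_out, file.path(out, "accounting.json"),
                       auto_unbox = TRUE, digits = NA)
  stage_log("account", t0,
            total_Mg = sprintf("%.1f", summ$total_biomass_Mg))

  invisible(list(responses = responses, variograms = vg,
                 model_comparison = comparison, minimal = minimal,
                 ensembles = ensembles, summary = summ,
                 accounting = acct, out_dir = out))
}
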