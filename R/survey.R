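valid_statuses <- c("fresh", "partially_eaten", "rotten", "dried",
                    "germinating")

#' Apply the fruit-fall inclusion rules
#'
#' Filters raw tallies down to the eligible counts used for biomass and
#' diversity: fresh and partially-eaten fruits are counted; rotten, dried
#' and germinating fruits are excluded. Across repeat visits
#' (`survey_month`), species flagged `removable` (fruits collected after
#' counting, so never seen twice) have their counts summed, while
#' non-removable species take the maximum monthly count so a fruit that
#' persists on the ground between visits is counted only once.
#'
#' @param records Long data.frame with columns `plot_id`, `species`,
#'   `status`, `count`, and optionally `survey_month` and `removable`.
#' @return Data.frame `plot_id`, `species`, `count` of eligible counts
#'   (species-plot combinations with a zero eligible count are dropped).
#' @export
#' @examples
#' obs <- data.frame(plot_id = "p1", species = c("a", "a", "b"),
#'                   status = c("fresh", "rotten", "partially_eaten"),
#'                   count = c(4, 5, 3))
#' apply_inclusion_rules(obs)  # a: 4, b: 3
apply_inclusion_rules <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("plot_id", "species", "status", "count") %in%
                  names(records)))
  bad <- setdiff(unique(records$status), valid_statuses)
  if (length(bad))
    stop(sprintf("unknown fruit status code(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  if (any(records$count < 0))
    stop("negative counts are not allowed", call. = FALSE)
  if (is.null(records$survey_month)) records$survey_month <- 1L
  if (is.null(records$removable)) records$removable <- FALSE
  eligible <- records[records$status %in% c("fresh", "partially_eaten"), ,
                      drop = FALSE]
  if (nrow(eligible) == 0)
    return(data.frame(plot_id = character(), species = character(),
                      count = numeric()))
  # counts per plot x species x month, then aggregate across months
  monthly <- stats::aggregate(
    count ~ plot_id + species + survey_month + removable, data = eligible,
    FUN = sum)
  agg <- do.call(rbind, lapply(
    split(monthly, list(monthly$plot_id, monthly$species), drop = TRUE),
    function(d) data.frame(
      plot_id = d$plot_id[1], species = d$species[1],
      count = if (d$removable[1]) sum(d$count) else max(d$count))))
  agg <- agg[agg$count > 0, , drop = FALSE]
  agg <- agg[order(agg$plot_id, agg$species), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Convert eligible fruit counts to dry biomass
#'
#' Dry biomass rate for one plot:
#' `sum(count * mean_dry_mass_g) / 1000 / (area_m2 / 1e4) / n_survey_months`
#' in kg ha^-1 month^-1.
#'
#' @param counts Data.frame `species`, `count` (eligible counts for one
#'   plot), or a named numeric vector of counts.
#' @param masses Species dry-mass table: data.frame `species`,
#'   `mean_dry_mass_g`.
#' @param area_m2 Plot area (m^2).
#' @param n_survey_months Survey window length (months); use 1 to keep the
#'   survey-period total.
#' @return Biomass in kg ha^-1 month^-1 (scalar, `>= 0`).
#' @export
#' @examples
#' m <- data.frame(species = "sp", mean_dry_mass_g = 18.2)
#' biomass_from_counts(c(sp = 10), m, area_m2 = 500)  # 3.64
biomass_from_counts <- function(counts, masses, area_m2,
                                n_survey_months = 1) {
  if (!is.data.frame(counts))
    counts <- data.frame(species = names(counts),
                         count = as.numeric(counts))
  stopifnot(area_m2 > 0, n_survey_months >= 1)
  if (nrow(counts) == 0) return(0)
  i <- match(counts$species, masses$species)
  if (anyNA(i))
    stop(sprintf("no dry-mass entry for species: %s",
                 paste(counts$species[is.na(i)], collapse = ", ")),
         call. = FALSE)
  if (any(masses$mean_dry_mass_g[i] <= 0))
    stop("mean dry mass must be positive", call. = FALSE)
  sum(counts$count * masses$mean_dry_mass_g[i]) / 1000 /
    (area_m2 / 1e4) / n_survey_months
}

#' Species richness per hectare
#'
#' Number of species with a positive eligible count, divided by the plot
#' area in hectares.
#'
#' @param counts As in [biomass_from_counts()].
#' @param area_m2 Plot area (m^2).
#' @return Species ha^-1.
#' @export
richness_per_ha <- function(counts, area_m2) {
  if (!is.data.frame(counts))
    counts <- data.frame(species = names(counts),
                         count = as.numeric(counts))
  stopifnot(area_m2 > 0)
  length(unique(counts$species[counts$count > 0])) / (area_m2 / 1e4)
}

#' Shannon diversity index (nats)
#'
#' `H = -sum(p_i * log(p_i))` over species proportions of the eligible
#' counts; 0 when at most one species is present; bounded by `log(S)`.
#'
#' @param counts As in [biomass_from_counts()].
#' @return H in nats.
#' @export
shannon_index <- function(counts) {
  if (is.data.frame(counts)) counts <- counts$count
  counts <- counts[counts > 0]
  if (length(counts) <= 1) return(0)
  p <- counts / sum(counts)
  -sum(p * log(p))
}

#' Species dominance ranking
#'
#' Ranks species by total dry biomass across all plots, with count and
#' biomass shares (%) and the number of plots where each species occurs.
#'
#' @param counts Filtered counts (output of [apply_inclusion_rules()]).
#' @param masses Species dry-mass table.
#' @return Data.frame `species`, `total_count`, `count_share_pct`,
#'   `total_biomass_g`, `biomass_share_pct`, `n_plots_present`, sorted by
#'   descending biomass. Shares sum to 100.
#' @export
species_dominance_table <- function(counts, masses) {
  stopifnot(is.data.frame(counts), nrow(counts) > 0)
  i <- match(counts$species, masses$species)
  if (anyNA(i))
    stop(sprintf("no dry-mass entry for species: %s",
                 paste(unique(counts$species[is.na(i)]), collapse = ", ")),
         call. = FALSE)
  counts$biomass_g <- counts$count * masses$mean_dry_mass_g[i]
  tot <- stats::aggregate(cbind(count, biomass_g) ~ species, data = counts,
                          FUN = sum)
  npl <- stats::aggregate(plot_id ~ species, data = counts[counts$count > 0, ],
                          FUN = function(z) length(unique(z)))
  out <- merge(tot, npl, by = "species")
  out <- data.frame(
    species = out$species,
    total_count = out$count,
    count_share_pct = 100 * out$count / sum(out$count),
    total_biomass_g = out$biomass_g,
    biomass_share_pct = 100 * out$biomass_g / sum(out$biomass_g),
    n_plots_present = out$plot_id)
  out <- out[order(-out$total_biomass_g, out$species), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the plot-level response table
#'
#' Joins the analysis responses (biomass, presence, richness, Shannon) with
#' the covariates extracted at each plot centroid. `biomass` is the focal
#' species' survey-period total per hectare (the model response;
#' `biomass_log1p` is its log1p transform for users preferring a
#' log-scale gaussian fit); `biomass_monthly` and
#' `biomass_overall_monthly` are the per-month rates of Table-1 style
#' summaries. Eligible counts are pooled across survey months by the
#' inclusion rules before richness and Shannon are computed.
#'
#' @param observations Raw tallies (see [apply_inclusion_rules()]).
#' @param plots Plot metadata: `plot_id`, `x`, `y`, `area_m2` (e.g.
#'   `design$plots`).
#' @param masses Species dry-mass table.
#' @param stack A [covariate_stack()] covering all plot centroids.
#' @param focal_species Species whose presence/biomass is modelled.
#' @param n_survey_months Survey window (months) used for the monthly rates.
#' @return Data.frame with one row per plot (row count preserved):
#'   responses, `Longitude`, `Latitude`, all covariate layers and `Basin`.
#' @export
build_response_table <- function(observations, plots, masses, stack,
                                 focal_species, n_survey_months = 2) {
  stopifnot(is.data.frame(plots),
            all(c("plot_id", "x", "y", "area_m2") %in% names(plots)))
  counts <- apply_inclusion_rules(observations)
  resp <- do.call(rbind, lapply(seq_len(nrow(plots)), function(i) {
    ci <- counts[counts$plot_id == plots$plot_id[i], , drop = FALSE]
    foc <- ci[ci$species == focal_species, , drop = FALSE]
    b_foc <- biomass_from_counts(foc, masses, plots$area_m2[i], 1)
    b_all <- biomass_from_counts(ci, masses, plots$area_m2[i], 1)
    data.frame(
      plot_id = plots$plot_id[i],
      biomass = b_foc,
      biomass_log1p = log1p(b_foc),
      biomass_monthly = b_foc / n_survey_months,
      biomass_overall_monthly = b_all / n_survey_months,
      presence = as.integer(sum(foc$count) > 0),
      richness_ha = richness_per_ha(ci, plots$area_m2[i]),
      shannon = shannon_index(ci))
  }))
  cov <- extract_at_points(stack, plots$x, plots$y)
  out <- cbind(resp, Longitude = plots$x, Latitude = plots$y, cov)
  rownames(out) <- NULL
  out
}
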