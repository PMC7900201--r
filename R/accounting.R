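#' Annualize a monthly fruit-fall rate
#'
#' Upper-bound extrapolation of a monthly rate to a yearly one
#' (`monthly x 12`). Masting is episodic, so this is a maximum, not a mean;
#' downstream reports store it as `annual_max`.
#'
#' @param monthly Rate in kg ha^-1 month^-1.
#' @return kg ha^-1 yr^-1.
#' @export
#' @examples
#' annualize_monthly_biomass(44.84)  # 538.08
annualize_monthly_biomass <- function(monthly) {
  stopifnot(all(monthly >= 0))
  monthly * 12
}

#' Landscape biomass total from a per-hectare rate
#'
#' @param rate kg ha^-1 yr^-1 (or any per-ha rate).
#' @param area_ha Landscape area (ha).
#' @return Total in Mg over the same period.
#' @export
landscape_total_biomass <- function(rate, area_ha) {
  stopifnot(area_ha > 0, all(rate >= 0))
  rate * area_ha / 1000
}

#' Above-ground-biomass reference bounds
#'
#' Minimum: sum of the mapped AGLB raster (`Mg ha^-1 x pixel area ha`).
#' Maximum: a published per-hectare mean extrapolated over the area.
#'
#' @param aglb Matrix of AGLB (Mg ha^-1) on the study grid, or `NULL` to
#'   skip the raster bound.
#' @param grid The [grid_spec()] of `aglb`.
#' @param per_ha_mean Published mean AGB (Mg ha^-1) for the maximum bound.
#' @param area_ha Study area (ha).
#' @return List `min_Mg` (NA without a raster), `max_Mg`.
#' @export
agb_reference_bounds <- function(aglb, grid, per_ha_mean, area_ha) {
  stopifnot(per_ha_mean > 0, area_ha > 0)
  min_Mg <- if (is.null(aglb)) NA_real_ else {
    stopifnot(inherits(grid, "grid_spec"),
              length(aglb) == grid$n_rows * grid$n_cols)
    sum(aglb * grid$pixel_area_ha)
  }
  list(min_Mg = min_Mg, max_Mg = per_ha_mean * area_ha)
}

#' Fruit-fall as a percentage of above-ground biomass
#'
#' @param fruit_total Fruit-fall biomass (Mg).
#' @param agb Above-ground biomass (Mg), `> 0`.
#' @return Percentage.
#' @export
#' @examples
#' fruitfall_to_agb_fraction(1345, 694005)  # 0.1938...
fruitfall_to_agb_fraction <- function(fruit_total, agb) {
  stopifnot(all(fruit_total >= 0))
  if (any(agb <= 0)) stop("AGB must be positive", call. = FALSE)
  100 * fruit_total / agb
}

#' Dry fruit mass shed per tree
#'
#' @param fruits_per_tree Fruit crop of one tree.
#' @param mean_fruit_dry_g Mean dry mass of one fruit (g).
#' @return kg per tree.
#' @export
#' @examples
#' per_tree_fruit_mass(4000, 18.2)  # 72.8
per_tree_fruit_mass <- function(fruits_per_tree, mean_fruit_dry_g) {
  stopifnot(all(fruits_per_tree >= 0), all(mean_fruit_dry_g >= 0))
  fruits_per_tree * mean_fruit_dry_g / 1000
}

#' Seed fraction of fruit dry mass
#'
#' @param seed_g,fruit_g Mean dry masses (g).
#' @return Fraction of the fruit mass in the seed.
#' @export
seed_mass_fraction <- function(seed_g, fruit_g) {
  stopifnot(all(seed_g >= 0))
  if (any(fruit_g <= 0)) stop("fruit mass must be positive", call. = FALSE)
  seed_g / fruit_g
}

#' Implied density of fruiting trees
#'
#' Divides an observed per-hectare fruit-fall biomass (over the masting
#' event) by the per-tree fruit mass.
#'
#' @param plot_biomass kg ha^-1 over the event.
#' @param per_tree_kg kg of dry fruit shed per tree.
#' @return Trees ha^-1.
#' @export
implied_fruiting_tree_density <- function(plot_biomass, per_tree_kg) {
  stopifnot(all(plot_biomass >= 0))
  if (any(per_tree_kg <= 0))
    stop("per-tree fruit mass must be positive", call. = FALSE)
  plot_biomass / per_tree_kg
}

#' Full up-scaling account
#'
#' Chains the accounting arithmetic: annualized maximum rate, landscape
#' annual total, fraction of the minimum AGB bound, masting-event total as
#' a fraction of both AGB bounds, per-tree fruit mass, seed fraction, and
#' implied fruiting-tree density for the plot maximum. All intermediate
#' values are retained unrounded.
#'
#' @param mean_monthly Plot-mean fruit-fall (kg ha^-1 month^-1).
#' @param area_ha Study area (ha).
#' @param masting_total_Mg Interpolated masting-event total (Mg).
#' @param agb_min_Mg,agb_max_Mg AGB bounds (Mg).
#' @param fruits_per_tree,fruit_mass_g,seed_mass_g Per-tree constants.
#' @param max_plot_monthly Largest plot rate (kg ha^-1 month^-1), for the
#'   implied-density range.
#' @param n_event_months Months spanned by the masting event.
#' @return Named list of class `upscaling_account`.
#' @export
upscaling_account <- function(mean_monthly, area_ha, masting_total_Mg,
                              agb_min_Mg, agb_max_Mg, fruits_per_tree,
                              fruit_mass_g, seed_mass_g,
                              max_plot_monthly = NA, n_event_months = 2) {
  annual_max <- annualize_monthly_biomass(mean_monthly)
  annual_total <- landscape_total_biomass(annual_max, area_ha)
  per_tree <- per_tree_fruit_mass(fruits_per_tree, fruit_mass_g)
  out <- list(
    mean_monthly_kg_ha = mean_monthly,
    annual_max_kg_ha_yr = annual_max,
    annual_total_Mg = annual_total,
    annual_agb_fraction_pct =
      fruitfall_to_agb_fraction(annual_total, agb_min_Mg),
    masting_total_Mg = masting_total_Mg,
    masting_agb_fraction_max_pct =
      fruitfall_to_agb_fraction(masting_total_Mg, agb_min_Mg),
    masting_agb_fraction_min_pct =
      fruitfall_to_agb_fraction(masting_total_Mg, agb_max_Mg),
    per_tree_kg = per_tree,
    seed_fraction = seed_mass_fraction(seed_mass_g, fruit_mass_g),
    implied_density_mean =
      implied_fruiting_tree_density(mean_monthly * n_event_months,
                                    per_tree),
    implied_density_max = if (is.na(max_plot_monthly)) NA_real_ else
      implied_fruiting_tree_density(max_plot_monthly * n_event_months,
                                    per_tree))
  class(out) <- c("upscaling_account", "list")
  out
}

#' @export
print.upscaling_account <- function(x, ...) {
  cat(sprintf("annual max: %.1f kg ha^-1 yr^-1 -> %.0f Mg yr^-1 (%.2f%% of min AGB)\n",
              x$annual_max_kg_ha_yr, x$annual_total_Mg,
              x$annual_agb_fraction_pct))
  cat(sprintf("masting event: %.1f Mg = %.2f-%.2f%% of AGB bounds\n",
              x$masting_total_Mg, x$masting_agb_fraction_min_pct,
              x$masting_agb_fraction_max_pct))
  cat(sprintf("per tree: %.1f kg dry fruit (seed fraction %.2f)\n",
              x$per_tree_kg, x$seed_fraction))
  invisible(x)
}
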