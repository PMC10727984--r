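#' Production from yield and harvested area
#'
#' @param yield_t_ha yield [grid_field()], t/ha.
#' @param area_ha harvested-area [grid_field()], ha.
#' @return production [grid_field()], t (`yield x area`; NA propagates).
#' @export
production <- function(yield_t_ha, area_ha) {
  stop_if_misaligned(yield_t_ha, area_ha, "yield and area grids")
  if (any(yield_t_ha$values < 0, na.rm = TRUE) || any(area_ha$values < 0, na.rm = TRUE)) {
    stop("yield and area must be nonnegative")
  }
  out <- yield_t_ha
  out$values <- yield_t_ha$values * area_ha$values
  out
}

#' Per-country production change
#'
#' @param baseline_prod,scenario_prod production [grid_field()]s, t.
#' @param country_id integer [grid_field()] of country ids.
#' @return data.frame with one row per country present on cells where both
#'   productions are non-missing: `country_id`, `baseline_t`, `scenario_t`,
#'   `change_pct` (`100 * (scenario - baseline) / baseline`; NA when the
#'   country's baseline is 0).
#' @export
country_change <- function(baseline_prod, scenario_prod, country_id) {
  stop_if_misaligned(baseline_prod, scenario_prod, "production grids")
  stop_if_misaligned(baseline_prod, country_id, "production and country grids")
  b <- baseline_prod$values; s <- scenario_prod$values
  ok <- !is.na(b) & !is.na(s)
  ctry <- as.integer(country_id$values[ok])
  if (anyNA(ctry)) stop("every cropland cell must have a country")
  base <- tapply(b[ok], ctry, sum)
  scen <- tapply(s[ok], ctry, sum)
  data.frame(
    country_id = as.integer(names(base)),
    baseline_t = as.numeric(base),
    scenario_t = as.numeric(scen),
    change_pct = ifelse(base == 0, NA_real_, 100 * (scen - base) / base),
    row.names = NULL
  )
}

#' Global production change
#'
#' @param baseline_prod,scenario_prod production [grid_field()]s, t.
#' @return scalar percentage change of total production (increases and
#'   decreases both counted).
#' @export
global_change <- function(baseline_prod, scenario_prod) {
  stop_if_misaligned(baseline_prod, scenario_prod, "production grids")
  b <- baseline_prod$values; s <- scenario_prod$values
  ok <- !is.na(b) & !is.na(s)
  total_b <- sum(b[ok])
  if (total_b == 0) stop("global baseline production is zero")
  100 * (sum(s[ok]) - total_b) / total_b
}

#' Share of each climate bin's area with a substantial yield loss
#'
#' For each bin, the harvested-area-weighted share of cells whose scenario
#' yield is at least `threshold` below baseline (scenario <= (1 - threshold)
#' x baseline). `weighting = "cells"` counts cells instead of weighting by
#' area.
#'
#' @param baseline_yield,scenario_yield yield [grid_field()]s, t/ha.
#' @param bins a `bin_assignment`.
#' @param area_ha harvested-area [grid_field()] (required for area
#'   weighting).
#' @param threshold fractional loss defining "impacted", default 0.10.
#' @param weighting `"area"` (default) or `"cells"`.
#' @return data.frame `bin_id`, `impacted_pct` in `[0, 100]`.
#' @export
bin_impact_extent <- function(baseline_yield, scenario_yield, bins,
                              area_ha = NULL, threshold = 0.10,
                              weighting = c("area", "cells")) {
  weighting <- match.arg(weighting)
  stop_if_misaligned(baseline_yield, scenario_yield, "yield grids")
  stop_if_misaligned(baseline_yield, bins$bin_id, "yield and bin grids")
  if (weighting == "area" && is.null(area_ha)) {
    stop("area weighting needs the harvested-area grid")
  }
  b <- baseline_yield$values; s <- scenario_yield$values
  bin <- bins$bin_id$values
  ok <- !is.na(b) & !is.na(s) & !is.na(bin)
  w <- if (weighting == "area") area_ha$values[ok] else rep(1, sum(ok))
  impacted <- s[ok] <= (1 - threshold) * b[ok]
  bin_ok <- as.integer(bin[ok])
  tot <- tapply(w, bin_ok, sum)
  hit <- tapply(w * impacted, bin_ok, sum)
  data.frame(bin_id = as.integer(names(tot)),
             impacted_pct = ifelse(tot > 0, 100 * as.numeric(hit) / as.numeric(tot),
                                   NA_real_),
             row.names = NULL)
}
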