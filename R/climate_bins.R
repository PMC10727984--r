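#' Crop climate specification
#'
#' Base and cutoff temperatures for growing-degree-day accumulation. The
#' defaults (base 8 degC, cutoff 30 degC) describe a temperate cereal; real
#' applications should supply crop-specific values.
#'
#' @param base_temp_C base temperature, degC; days at or below it contribute 0.
#' @param cutoff_temp_C ceiling temperature, degC; warmer days count as if at
#'   the cutoff.
#' @return a `crop_climate_spec` list.
#' @export
crop_climate_spec <- function(base_temp_C = 8, cutoff_temp_C = 30) {
  if (cutoff_temp_C <= base_temp_C) stop("cutoff_temp_C must exceed base_temp_C")
  structure(list(base_temp_C = base_temp_C, cutoff_temp_C = cutoff_temp_C),
            class = "crop_climate_spec")
}

#' Growing degree days from daily temperature
#'
#' For each day with temperature above the base, the contribution is
#' `min(T, cutoff) - base` (the standard degree-day definition); annual sums
#' are averaged over the years of record. `contribution = "raw"` instead sums
#' the capped temperature itself on qualifying days, for sensitivity checks
#' against the alternative reading of "summing the temperature".
#'
#' @param daily_temps numeric vector or cells x days matrix of daily mean
#'   temperature, degC; the number of days must be a multiple of
#'   `days_per_year`.
#' @param spec a [crop_climate_spec()].
#' @param days_per_year days per (model) year, default 365.
#' @param contribution "above_base" (default) or "raw".
#' @return mean annual GDD: a scalar for vector input, a per-cell vector for
#'   matrix input.
#' @export
growing_degree_days <- function(daily_temps, spec = crop_climate_spec(),
                                days_per_year = 365L,
                                contribution = c("above_base", "raw")) {
  contribution <- match.arg(contribution)
  stopifnot(inherits(spec, "crop_climate_spec"))
  vec_in <- !is.matrix(daily_temps)
  m <- if (vec_in) matrix(daily_temps, nrow = 1L) else daily_temps
  if (ncol(m) == 0L) stop("empty temperature series")
  if (ncol(m) %% days_per_year != 0L) {
    stop("number of days is not a whole number of years")
  }
  n_years <- ncol(m) %/% days_per_year
  capped <- pmin(m, spec$cutoff_temp_C)
  contrib <- if (contribution == "above_base") {
    pmax(capped - spec$base_temp_C, 0)
  } else {
    ifelse(m > spec$base_temp_C, capped, 0)
  }
  # annual sums, then mean over years
  dim(contrib) <- c(nrow(m), days_per_year, n_years)
  ann <- colSums(aperm(contrib, c(2L, 1L, 3L)))   # cells x years
  out <- rowMeans(matrix(ann, nrow = nrow(m)))
  if (vec_in) out[[1L]] else out
}

#' Mean annual cumulative precipitation
#'
#' @param daily_precip numeric vector or cells x days matrix of daily
#'   precipitation, mm.
#' @param days_per_year days per (model) year, default 365.
#' @return mm/yr: mean over years of the annual sums; scalar for vector input.
#' @export
annual_precipitation <- function(daily_precip, days_per_year = 365L) {
  vec_in <- !is.matrix(daily_precip)
  m <- if (vec_in) matrix(daily_precip, nrow = 1L) else daily_precip
  if (ncol(m) == 0L) stop("empty precipitation series")
  if (ncol(m) %% days_per_year != 0L) {
    stop("number of days is not a whole number of years")
  }
  n_years <- ncol(m) %/% days_per_year
  n_cells <- nrow(m)
  dim(m) <- c(n_cells, days_per_year, n_years)
  ann <- colSums(aperm(m, c(2L, 1L, 3L)))         # cells x years
  out <- rowMeans(matrix(ann, nrow = n_cells))
  if (vec_in) out[[1L]] else out
}

# marginal quintile of each value among masked cells; ties broken by first
# appearance (row-major cell index), so counts stay within floor/ceiling(N/5)
marginal_quintile <- function(values, n_groups = 5L) {
  r <- rank(values, ties.method = "first")
  n <- length(values)
  as.integer(ceiling(r * n_groups / n))
}

#' Stratify cropland into 25 climate bins
#'
#' GDD and precipitation climatologies are each split into quintiles over the
#' cropland cells of the crop in question; a cell's bin is the pair of its
#' marginal quintiles, `bin = 5 * (gdd_quintile - 1) + precip_quintile`
#' (1..25). Quintiles are rank-based, so the assignment is invariant to any
#' strictly monotone transform of either climatology; marginal counts are
#' N/5 rounded, joint counts only approximately equal.
#'
#' @param gdd_clim,precip_clim climatology [grid_field()]s.
#' @param mask logical matrix, TRUE on cropland.
#' @return a `bin_assignment`: `bin_id` ([grid_field()], NA off cropland),
#'   `gdd_edges`, `precip_edges` (the 4 interior quintile thresholds, type-7
#'   quantiles), and the input climatologies.
#' @export
assign_climate_bins <- function(gdd_clim, precip_clim, mask) {
  stop_if_misaligned(gdd_clim, precip_clim, "climatologies")
  stopifnot(is.logical(mask), identical(dim(mask), dim(gdd_clim$values)))
  g <- gdd_clim$values[mask]
  p <- precip_clim$values[mask]
  if (length(g) < 25) stop("fewer cropland cells than climate bins")
  if (any(!is.finite(g)) || any(!is.finite(p))) {
    stop("climatologies must be finite on the cropland mask")
  }
  if (max(g) == min(g) || max(p) == min(p)) {
    stop("degenerate climatology: all cropland cells share one value")
  }
  qg <- marginal_quintile(g)
  qp <- marginal_quintile(p)
  bin <- 5L * (qg - 1L) + qp
  bin_id <- gdd_clim
  bin_id$values[] <- NA_real_
  bin_id$values[mask] <- bin
  structure(
    list(bin_id = bin_id,
         gdd_edges = stats::quantile(g, c(.2, .4, .6, .8), names = FALSE),
         precip_edges = stats::quantile(p, c(.2, .4, .6, .8), names = FALSE),
         gdd_clim = gdd_clim, precip_clim = precip_clim),
    class = "bin_assignment"
  )
}

#' @export
print.bin_assignment <- function(x, ...) {
  b <- x$bin_id$values
  cat(sprintf("<bin_assignment> %d cropland cells in %d climate bins\n",
              sum(!is.na(b)), length(unique(b[!is.na(b)]))))
  cat("  GDD edges:    ", paste(signif(x$gdd_edges, 4), collapse = ", "), "\n")
  cat("  precip edges: ", paste(signif(x$precip_edges, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Climate climatologies of a crop world
#'
#' Convenience wrapper: computes per-cell mean annual GDD and precipitation
#' from a world's daily climate and assigns climate bins over its cropland.
#'
#' @param world a `crop_world`.
#' @param spec a [crop_climate_spec()].
#' @return a `bin_assignment` (see [assign_climate_bins()]).
#' @export
bin_world <- function(world, spec = crop_climate_spec()) {
  stopifnot(inherits(world, "crop_world"))
  dpy <- attr(world$daily_temp_C, "days_per_year")
  n <- world$config$grid_rows; p <- world$config$grid_cols
  gf <- function(v) grid_field(matrix(v, n, p, byrow = TRUE),
                               xmin = world$yield$xmin, ymax = world$yield$ymax,
                               cell_size = world$yield$cell_size)
  gdd <- gf(growing_degree_days(world$daily_temp_C, spec, days_per_year = dpy))
  pre <- gf(annual_precipitation(world$daily_precip_mm, days_per_year = dpy))
  assign_climate_bins(gdd, pre, crop_mask(world))
}
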