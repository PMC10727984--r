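#' Mean of high and low pesticide application-rate estimates
#'
#' @param high,low aligned [grid_field()]s, kg/ha.
#' @return cellwise `(high + low) / 2` as a [grid_field()].
#' @export
pesticide_mean_estimate <- function(high, low) {
  stop_if_misaligned(high, low, "pesticide estimate grids")
  out <- high
  out$values <- (high$values + low$values) / 2
  out
}

#' Rescale a pesticide application rate to [0, 1]
#'
#' Divides every cell by the 97.5th percentile of the rate over the cropland
#' cells of the crop (linear-interpolation quantile, R type 7) and caps at 1,
#' so heavy-tail application rates do not dominate when group members are
#' summed. A field that is zero everywhere maps to zero everywhere.
#'
#' @param rate nonnegative [grid_field()].
#' @param mask optional logical matrix restricting the percentile to cropland
#'   cells; default uses every non-NA cell.
#' @param probs percentile used for the ceiling, default 0.975.
#' @return [grid_field()] with values in `[0, 1]`.
#' @export
rescale_pesticide <- function(rate, mask = NULL, probs = 0.975) {
  v <- rate$values
  sel <- if (is.null(mask)) !is.na(v) else mask & !is.na(v)
  vals <- v[sel]
  if (!length(vals)) stop("no cells to compute the rescaling percentile over")
  if (any(vals < 0)) stop("pesticide rates must be nonnegative")
  q <- stats::quantile(vals, probs, names = FALSE, type = 7)
  out <- rate
  out$values <- if (q == 0) v * 0 else pmin(v / q, 1)
  out
}

#' Sum rescaled pesticide layers into the four pesticide groups
#'
#' @param rescaled named list of rescaled [grid_field()]s (each in `[0, 1]`).
#' @param group_map named character vector: pesticide name -> group, groups
#'   drawn from Herbicides, Insecticides, Fungicides, Others.
#' @return named list of 4 [grid_field()]s (`pest_herbicide`,
#'   `pest_insecticide`, `pest_fungicide`, `pest_other`); a group with no
#'   members is all zeros.
#' @export
group_pesticides <- function(rescaled, group_map) {
  groups <- c(Herbicides = "pest_herbicide", Insecticides = "pest_insecticide",
              Fungicides = "pest_fungicide", Others = "pest_other")
  if (!all(group_map %in% names(groups))) {
    stop("group_map values must be Herbicides/Insecticides/Fungicides/Others")
  }
  missing <- setdiff(names(rescaled), names(group_map))
  if (length(missing)) {
    stop("pesticides missing from group map: ", paste(missing, collapse = ", "))
  }
  template <- rescaled[[1L]]
  out <- lapply(seq_along(groups), function(i) {
    members <- names(group_map)[group_map == names(groups)[i]]
    members <- intersect(members, names(rescaled))
    acc <- template
    acc$values <- acc$values * 0
    for (m in members) {
      stop_if_misaligned(template, rescaled[[m]], "pesticide grids")
      acc$values <- acc$values + rescaled[[m]]$values
    }
    acc
  })
  names(out) <- unname(groups)
  out
}

#' Fill missing country machinery values from continent averages
#'
#' @param country_values named numeric vector, country id -> value (hp per
#'   1,000 ha); `NA` marks countries without data.
#' @param continent_of named vector mapping every country id to its continent.
#' @return completed named numeric vector in the same order; missing countries
#'   receive the unweighted mean of their continent's observed values.
#' @export
fill_machinery <- function(country_values, continent_of) {
  if (!all(names(country_values) %in% names(continent_of))) {
    stop("every country must have a continent")
  }
  cont <- continent_of[names(country_values)]
  out <- country_values
  for (cc in unique(cont[is.na(country_values)])) {
    have <- country_values[cont == cc & !is.na(country_values)]
    if (!length(have)) stop(sprintf("continent '%s' has no machinery data at all", cc))
    out[cont == cc & is.na(country_values)] <- mean(have)
  }
  out
}

#' Share of harvested area under irrigation
#'
#' @param irrigated,total aligned harvested-area [grid_field()]s, ha.
#' @return percentage [grid_field()]; 0 where the total is 0.
#' @export
irrigation_share <- function(irrigated, total) {
  stop_if_misaligned(irrigated, total, "harvested-area grids")
  iv <- irrigated$values; tv <- total$values
  if (any(iv < 0, na.rm = TRUE) || any(tv < 0, na.rm = TRUE)) {
    stop("areas must be nonnegative")
  }
  if (any(iv > tv & tv > 0, na.rm = TRUE)) {
    stop("irrigated area exceeds total harvested area")
  }
  out <- total
  out$values <- ifelse(tv > 0, 100 * iv / tv, 0)
  out$values[is.na(iv) | is.na(tv)] <- NA_real_
  out
}

#' Aggregate a fine soil-density grid to the model grid as a t/ha stock
#'
#' Converts topsoil density (hg/m3) to a per-hectare stock over the given
#' depth — `stock [t/ha] = density [hg/m3] x depth [m]` after unit
#' cancellation (0.0001 t/hg x 10,000 m2/ha = 1) — and block-averages the
#' fine grid into coarse cells.
#'
#' @param density fine-resolution [grid_field()], hg/m3.
#' @param depth_m soil depth, m (default 0.3, topsoil 0-30 cm).
#' @param factor integer aggregation factor; fine dims must be exact
#'   multiples of it.
#' @return coarse [grid_field()], t/ha (mean of the fine cells, then
#'   converted).
#' @export
soil_to_t_ha <- function(density, depth_m = 0.3, factor = 1L) {
  stopifnot(depth_m > 0)
  factor <- as.integer(factor)
  v <- density$values
  if (nrow(v) %% factor != 0L || ncol(v) %% factor != 0L) {
    stop("fine grid is not an integer multiple of the aggregation factor")
  }
  if (factor > 1L) {
    nr <- nrow(v) %/% factor; nc <- ncol(v) %/% factor
    idx_r <- (seq_len(nrow(v)) - 1L) %/% factor
    idx_c <- (seq_len(ncol(v)) - 1L) %/% factor
    agg <- matrix(0, nr, nc)
    cnt <- matrix(0, nr, nc)
    for (i in seq_len(nrow(v))) {
      s <- tapply(v[i, ], idx_c, sum)
      n_ok <- tapply(!is.na(v[i, ]), idx_c, sum)
      s[is.na(s)] <- 0
      agg[idx_r[i] + 1L, ] <- agg[idx_r[i] + 1L, ] + s
      cnt[idx_r[i] + 1L, ] <- cnt[idx_r[i] + 1L, ] + n_ok
    }
    v <- ifelse(cnt > 0, agg / cnt, NA_real_)
  }
  grid_field(v * depth_m, xmin = density$xmin, ymax = density$ymax,
             cell_size = density$cell_size * factor)
}

#' Assemble the per-cell model feature table
#'
#' One row per cropland cell: grid position, climate bin, the model
#' covariates (see [model_covariates()]), harvested area, country, and yield.
#' Rows are partitioned by `bin_id`; the per-bin tables are the random-forest
#' training frames.
#'
#' @param world a `crop_world`.
#' @param bins a `bin_assignment` for the same grid.
#' @return data.frame with columns `cell`, `row`, `col`, `bin_id`,
#'   `country_id`, `harvested_area`, the covariates, and `yield`.
#' @export
build_feature_table <- function(world, bins) {
  stopifnot(inherits(world, "crop_world"), inherits(bins, "bin_assignment"))
  stop_if_misaligned(world$yield, bins$bin_id, "world and bin grids")
  mask <- crop_mask(world)
  idx <- which(mask)                       # column-major cell indices
  nr <- nrow(mask)
  df <- data.frame(
    cell = idx,
    row = ((idx - 1L) %% nr) + 1L,
    col = ((idx - 1L) %/% nr) + 1L,
    bin_id = as.integer(bins$bin_id$values[idx]),
    country_id = as.integer(world$country_id$values[idx]),
    harvested_area = world$harvested_area$values[idx]
  )
  for (nm in model_covariates()) {
    f <- world$covariates[[nm]]
    if (is.null(f)) stop(sprintf("covariate '%s' missing from world", nm))
    col <- f$values[idx]
    if (anyNA(col)) stop(sprintf("covariate '%s' has missing values on cropland", nm))
    df[[nm]] <- col
  }
  df$yield <- world$yield$values[idx]
  if (anyNA(df$yield)) stop("yield missing on cropland cells")
  df
}
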