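#' Configuration for the synthetic gridded world
#'
#' The generator emulates the statistical structure the shock analysis assumes
#' in real data: spatially autocorrelated, mutually correlated input rates;
#' country-constant machinery and labour; daily climate with a latitudinal
#' gradient and seasonal cycle; and a known saturating yield response so
#' counterfactual predictions can be compared with ground truth.
#'
#' @param grid_rows,grid_cols cell counts; their product must be at least 625
#'   so that 25 climate bins can be populated.
#' @param cell_size_deg cell size in degrees.
#' @param n_countries number of countries, laid out as contiguous rectangular
#'   blocks; must admit an a x b rectangular decomposition (25 -> 5 x 5).
#' @param n_continents number of continents; countries are grouped into
#'   continents by consecutive id.
#' @param n_years years of daily climate (365-day years).
#' @param noise_cv coefficient of variation of the multiplicative lognormal
#'   yield noise; 0 gives exactly the deterministic response.
#' @param cropland_fraction fraction of cells carrying the crop (harvested
#'   area > 0); the rest are non-cropland (area 0, yield NA).
#' @param seed integer seed; identical configs give bit-identical worlds.
#' @param response_params true yield response, see [response_params()].
#'
#' @return a `world_config` list.
#' @export
world_config <- function(grid_rows = 50, grid_cols = 50, cell_size_deg = 0.5,
                         n_countries = 100, n_continents = 5, n_years = 21,
                         noise_cv = 0.10, cropland_fraction = 0.9,
                         seed = 1L, response_params = NULL) {
  stopifnot(grid_rows >= 1, grid_cols >= 1, n_years >= 1, noise_cv >= 0,
            cropland_fraction > 0, cropland_fraction <= 1,
            n_continents >= 1, n_countries >= n_continents)
  if (grid_rows * grid_cols < 625) {
    stop("grid too small: need grid_rows * grid_cols >= 625 so all 25 climate bins are populated")
  }
  if (is.null(response_params)) response_params <- agrishock::response_params()
  stopifnot(inherits(response_params, "response_params"))
  structure(
    list(grid_rows = as.integer(grid_rows), grid_cols = as.integer(grid_cols),
         cell_size_deg = cell_size_deg, n_countries = as.integer(n_countries),
         n_continents = as.integer(n_continents), n_years = as.integer(n_years),
         noise_cv = noise_cv, cropland_fraction = cropland_fraction,
         seed = as.integer(seed), response_params = response_params),
    class = "world_config"
  )
}

#' True yield response parameters
#'
#' The deterministic response is Mitscherlich-type: each shockable input i
#' contributes a saturating factor
#' `floor_i + (1 - floor_i) * (1 - exp(-k_i * x_i * (1 + gamma * irrigation/100)))`,
#' multiplied together with a monotone soil-carbon multiplier
#' `g = 1 - soil_depress * exp(-soil_oc / soil_scale)` and the attainable
#' yield. Floors keep yield positive when an input is absent (other agronomic
#' pathways still deliver part of the attainable yield); `gamma` encodes that
#' the same input does more on irrigated land.
#'
#' @param k per-input rate constants, named by shockable covariate; units are
#'   the reciprocal of each input's unit.
#' @param floor per-input response floors in `[0, 1)`.
#' @param gamma irrigation interaction strength (>= 0).
#' @param soil_depress,soil_scale soil multiplier parameters; `soil_scale` in
#'   t/ha of soil organic carbon.
#' @return a `response_params` list.
#' @export
response_params <- function(
    k = c(n_rate = 0.015, p_rate = 0.07, k_rate = 0.025, machinery = 0.010,
          pest_herbicide = 0.8, pest_insecticide = 0.8,
          pest_fungicide = 0.8, pest_other = 0.8),
    floor = c(n_rate = 0.35, p_rate = 0.45, k_rate = 0.45, machinery = 0.60,
              pest_herbicide = 0.75, pest_insecticide = 0.75,
              pest_fungicide = 0.75, pest_other = 0.75),
    gamma = 0.5, soil_depress = 0.25, soil_scale = 40) {
  if (any(k < 0) || any(floor < 0) || gamma < 0 || soil_depress < 0 || soil_scale <= 0) {
    stop("response parameters must be nonnegative (soil_scale positive)")
  }
  if (any(floor >= 1)) stop("response floors must be < 1")
  if (!identical(sort(names(k)), sort(names(floor)))) {
    stop("k and floor must be named over the same inputs")
  }
  structure(list(k = k, floor = floor, gamma = gamma,
                 soil_depress = soil_depress, soil_scale = soil_scale),
            class = "response_params")
}

#' Covariates a shock scenario may touch
#' @return character vector of the 8 shockable covariate names.
#' @export
shockable_covariates <- function() {
  c("n_rate", "p_rate", "k_rate", "machinery",
    "pest_herbicide", "pest_insecticide", "pest_fungicide", "pest_other")
}

#' Model covariates (shockable inputs plus frozen controls)
#' @return character vector of the 14 covariate names used by the yield models.
#' @export
model_covariates <- function() {
  c("n_rate", "p_rate", "k_rate", "nonmineral_fert", "machinery", "labour",
    "pest_herbicide", "pest_insecticide", "pest_fungicide", "pest_other",
    "irrigation_share", "soil_n", "soil_p", "soil_oc")
}

# ---- spatial helpers ---------------------------------------------------------

# box-filter mean via integral image; edge windows renormalized by true count
box_mean <- function(m, radius) {
  n <- nrow(m); p <- ncol(m)
  S <- matrix(0, n + 1L, p + 1L)
  S[-1L, -1L] <- t(apply(apply(m, 2L, cumsum), 1L, cumsum))
  lo_r <- pmax(seq_len(n) - radius, 1L); hi_r <- pmin(seq_len(n) + radius, n)
  lo_c <- pmax(seq_len(p) - radius, 1L); hi_c <- pmin(seq_len(p) + radius, p)
  sums <- S[hi_r + 1L, hi_c + 1L, drop = FALSE] -
    S[lo_r, hi_c + 1L, drop = FALSE] -
    S[hi_r + 1L, lo_c, drop = FALSE] +
    S[lo_r, lo_c, drop = FALSE]
  counts <- outer(hi_r - lo_r + 1L, hi_c - lo_c + 1L)
  sums / counts
}

# smoothed standard-normal-ish field: white noise, box-smoothed, re-standardized
smooth_noise <- function(n, p, radius = 3L, passes = 2L) {
  m <- matrix(stats::rnorm(n * p), n, p)
  for (i in seq_len(passes)) m <- box_mean(m, radius)
  (m - mean(m)) / stats::sd(m)
}

# contiguous rectangular country blocks; n must factor as a x b
country_layout <- function(rows, cols, n_countries) {
  a <- floor(sqrt(n_countries))
  while (a > 1L && n_countries %% a != 0L) a <- a - 1L
  b <- n_countries %/% a
  band_r <- pmin(ceiling(seq_len(rows) / (rows / a)), a)
  band_c <- pmin(ceiling(seq_len(cols) / (cols / b)), b)
  outer(band_r, band_c, function(i, j) (i - 1L) * b + j)
}

# ---- generator ---------------------------------------------------------------

#' Generate a synthetic crop world
#'
#' Draws every layer of a [world_config()] world in a fixed order from one
#' seed, so equal configs give bit-identical worlds. The realized yield is
#' `potential_yield * response(inputs) * noise`, recorded exactly in the
#' attached truth record for counterfactual ground truth.
#'
#' @param config a [world_config()].
#' @return an object of class `crop_world` with elements `yield`,
#'   `harvested_area`, `covariates` (named list of [grid_field()]s),
#'   `country_id`, `continent_id`, `daily_temp_C`, `daily_precip_mm`
#'   (cells x days matrices, 365-day years), `config`, and `truth`
#'   (class `truth_record`: `potential_yield`, `noise_field`,
#'   `response_params`).
#' @export
generate_world <- function(config = world_config()) {
  stopifnot(inherits(config, "world_config"))
  set.seed(config$seed)
  n <- config$grid_rows; p <- config$grid_cols; n_cells <- n * p
  gf <- function(v) grid_field(v, xmin = 0, ymax = 60, cell_size = config$cell_size_deg)

  lat <- 60 - config$cell_size_deg * (seq_len(n) - 0.5)
  lat_m <- matrix(lat, n, p)

  # --- daily climate: latitudinal mean + seasonal cycle + weather noise
  n_days <- 365L * config$n_years
  doy <- rep(seq_len(365L), config$n_years)
  t_mean <- 30 - 0.45 * lat_m + 1.5 * smooth_noise(n, p, radius = 2L)
  t_amp <- 4 + 0.25 * lat_m
  seasonal <- cos(2 * pi * (doy - 196) / 365)
  # cells in row-major order (row 1 col 1, row 1 col 2, ...)
  cell_mean <- as.vector(t(t_mean)); cell_amp <- as.vector(t(t_amp))
  daily_temp <- outer(cell_mean, rep(1, n_days)) +
    outer(cell_amp, seasonal) +
    matrix(stats::rnorm(n_cells * n_days, sd = 3), n_cells, n_days)

  # patchy precipitation, statistically independent of the latitudinal
  # temperature field, so joint climate bins stay populated and no climate
  # quintile aliases with the spatial blocking grid
  precip_ann <- pmax(1500 * stats::plogis(
    0.9 * smooth_noise(n, p, radius = 2L) +
      0.4 * (matrix(seq_len(p), n, p, byrow = TRUE) / p - 0.5)
  ), 60)
  daily_precip <- matrix(
    stats::rexp(n_cells * n_days, rate = 1),
    n_cells, n_days
  ) * (as.vector(t(precip_ann)) / 365)
  attr(daily_temp, "days_per_year") <- 365L
  attr(daily_precip, "days_per_year") <- 365L

  # --- countries / continents
  country <- country_layout(n, p, config$n_countries)
  per_cont <- ceiling(config$n_countries / config$n_continents)
  continent <- matrix(pmin((country - 1L) %/% per_cont + 1L, config$n_continents), n, p)

  # --- mutually correlated, spatially autocorrelated input rates:
  # a shared latent fertility field induces positive cross-correlations
  fert_latent <- smooth_noise(n, p, radius = 2L)
  z <- function(r = 2L) smooth_noise(n, p, radius = r)
  n_rate <- 120 * exp(0.85 * fert_latent + 0.15 * z())
  p_rate <- 25 * exp(0.85 * fert_latent + 0.15 * z())
  k_rate <- 60 * exp(0.85 * fert_latent + 0.15 * z())
  nonmineral_fert <- 40 * exp(0.4 * z())
  pest <- lapply(1:4, function(i) 4 * stats::plogis(0.9 * fert_latent + 0.45 * z()))
  names(pest) <- c("pest_herbicide", "pest_insecticide", "pest_fungicide", "pest_other")
  irrigation_share <- 100 * stats::plogis(1.5 * z(3L))
  soil_n <- 3 * exp(0.3 * z())
  soil_p <- 50 * exp(0.3 * z())
  soil_oc <- 60 * exp(0.4 * z(3L))

  # --- country-constant mechanization and labour
  cont_mach <- exp(stats::rnorm(config$n_continents, log(60), 0.6))
  ctry_mach <- cont_mach[pmin((seq_len(config$n_countries) - 1L) %/% per_cont + 1L,
                              config$n_continents)] *
    exp(stats::rnorm(config$n_countries, 0, 0.4))
  ctry_lab <- 2000 / ctry_mach * exp(stats::rnorm(config$n_countries, 0, 0.3))
  machinery <- matrix(ctry_mach[country], n, p)
  labour <- matrix(ctry_lab[country], n, p)

  # --- cropland mask and harvested area
  crop_score <- smooth_noise(n, p, radius = 2L)
  thr <- stats::quantile(crop_score, 1 - config$cropland_fraction, names = FALSE)
  is_crop <- crop_score >= thr
  harvested_area <- ifelse(is_crop, 1000 * exp(0.5 * stats::rnorm(n_cells)), 0)
  harvested_area <- matrix(harvested_area, n, p)

  # --- attainable yield: mild climate suitability so most within-bin yield
  # variance is carried by the inputs (as the per-bin models assume)
  t_season <- 30 - 0.45 * lat_m   # without the local anomaly
  suit <- 0.85 + 0.3 * stats::plogis((t_season - 8) / 5)
  potential_yield <- 9 * suit * exp(0.05 * z())

  # --- multiplicative lognormal noise with E[eps] = 1 and CV = noise_cv
  sdlog <- sqrt(log(1 + config$noise_cv^2))
  eps <- matrix(stats::rlnorm(n_cells, meanlog = -sdlog^2 / 2, sdlog = sdlog), n, p)

  covariates <- c(
    list(n_rate = n_rate, p_rate = p_rate, k_rate = k_rate,
         nonmineral_fert = nonmineral_fert, machinery = machinery, labour = labour),
    pest,
    list(irrigation_share = irrigation_share, soil_n = soil_n, soil_p = soil_p,
         soil_oc = soil_oc)
  )
  covariates <- lapply(covariates, gf)

  truth <- structure(
    list(potential_yield = gf(potential_yield), noise_field = gf(eps),
         response_params = config$response_params),
    class = "truth_record"
  )
  yield <- true_yield(covariates, truth$potential_yield,
                      config$response_params, truth$noise_field)
  yield$values[!is_crop] <- NA_real_
  if (sum(is_crop) < 25) stop("generated world has fewer than 25 cropland cells")

  structure(
    list(yield = yield, harvested_area = gf(harvested_area),
         covariates = covariates,
         country_id = gf(country), continent_id = gf(continent),
         daily_temp_C = daily_temp, daily_precip_mm = daily_precip,
         config = config, truth = truth),
    class = "crop_world"
  )
}

#' @export
print.crop_world <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<crop_world> %d x %d cells (%.3g deg), %d cropland cells\n",
              cfg$grid_rows, cfg$grid_cols, cfg$cell_size_deg,
              sum(x$harvested_area$values > 0)))
  cat(sprintf("  %d countries / %d continents, %d years daily climate, noise CV %.2f, seed %d\n",
              cfg$n_countries, cfg$n_continents, cfg$n_years, cfg$noise_cv, cfg$seed))
  invisible(x)
}

#' Cropland mask of a crop world
#' @param world a `crop_world`.
#' @return logical matrix, TRUE where harvested area > 0.
#' @export
crop_mask <- function(world) world$harvested_area$values > 0

# ---- true response -----------------------------------------------------------

#' Evaluate the deterministic yield response (with optional noise)
#'
#' @param covariates named list of [grid_field()]s; must contain every input
#'   named in `params$k`, plus `irrigation_share` and `soil_oc`.
#' @param potential_yield attainable yield [grid_field()], t/ha.
#' @param params a [response_params()].
#' @param noise_field multiplicative noise [grid_field()], or NULL for the
#'   pure deterministic response.
#' @return yield [grid_field()], t/ha.
#' @export
true_yield <- function(covariates, potential_yield, params, noise_field = NULL) {
  stopifnot(inherits(params, "response_params"))
  irr <- covariates$irrigation_share$values
  boost <- 1 + params$gamma * irr / 100
  resp <- potential_yield$values
  for (nm in names(params$k)) {
    x <- covariates[[nm]]
    if (is.null(x)) stop(sprintf("covariate '%s' missing from world", nm))
    f <- params$floor[[nm]] +
      (1 - params$floor[[nm]]) * (1 - exp(-params$k[[nm]] * x$values * boost))
    resp <- resp * f
  }
  g <- 1 - params$soil_depress * exp(-covariates$soil_oc$values / params$soil_scale)
  resp <- resp * g
  if (!is.null(noise_field)) resp <- resp * noise_field$values
  out <- potential_yield
  out$values <- resp
  out
}

#' Ground-truth counterfactual yield under a shock scenario
#'
#' Re-evaluates the true response with shocked inputs and the SAME realized
#' noise as the baseline, so the baseline/scenario difference is purely the
#' deterministic input effect.
#'
#' @param world a `crop_world` from [generate_world()].
#' @param scenario a [shock_scenario()].
#' @return yield [grid_field()]; NA off cropland.
#' @export
true_counterfactual <- function(world, scenario) {
  stopifnot(inherits(world, "crop_world"), inherits(scenario, "shock_scenario"))
  covs <- world$covariates
  for (nm in scenario$shocked_covariates) {
    covs[[nm]]$values <- covs[[nm]]$values * (1 - scenario$severity)
  }
  y <- true_yield(covs, world$truth$potential_yield,
                  world$truth$response_params, world$truth$noise_field)
  y$values[!crop_mask(world)] <- NA_real_
  y
}
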