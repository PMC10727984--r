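# dense text matrix helpers for the daily climate layers (full precision)
write_matrix_txt <- function(m, path) {
  hdr <- sprintf("# %d %d %d", nrow(m), ncol(m),
                 as.integer(attr(m, "days_per_year") %||% 0L))
  body <- apply(m, 1L, function(r) paste(sprintf("%.17g", r), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

read_matrix_txt <- function(path) {
  lines <- readLines(path)
  hd <- as.integer(strsplit(sub("^# ", "", lines[[1L]]), " ")[[1L]])
  m <- matrix(scan(text = lines[-1L], what = double(), quiet = TRUE),
              nrow = hd[[1L]], ncol = hd[[2L]], byrow = TRUE)
  if (hd[[3L]] > 0L) attr(m, "days_per_year") <- hd[[3L]]
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a crop world to a directory of plain-text layers
#'
#' Every raster layer becomes an ESRI ASCII grid, the daily climate two dense
#' text matrices, the configuration a YAML file, and the truth record's
#' response parameters JSON. Values are written at full double precision so a
#' round trip is exact.
#'
#' @param world a `crop_world`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wa <- function(f, nm) write_ascii_grid(f, file.path(dir, paste0(nm, ".asc")))
  wa(world$yield, "yield")
  wa(world$harvested_area, "harvested_area")
  for (nm in names(world$covariates)) wa(world$covariates[[nm]], nm)
  wa(world$country_id, "country_id")
  wa(world$continent_id, "continent_id")
  wa(world$truth$potential_yield, "truth_potential_yield")
  wa(world$truth$noise_field, "truth_noise_field")
  write_matrix_txt(world$daily_temp_C, file.path(dir, "daily_temp_C.txt"))
  write_matrix_txt(world$daily_precip_mm, file.path(dir, "daily_precip_mm.txt"))
  cfg <- world$config
  cfg$response_params <- lapply(unclass(cfg$response_params), as.list)
  yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Read a crop world written by [write_world()]
#'
#' @param dir directory produced by [write_world()].
#' @return a `crop_world`.
#' @export
read_world <- function(dir) {
  ra <- function(nm) read_ascii_grid(file.path(dir, paste0(nm, ".asc")))
  cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))
  rp <- cfg$response_params
  cfg$response_params <- response_params(
    k = unlist(rp$k), floor = unlist(rp$floor), gamma = rp$gamma[[1L]],
    soil_depress = rp$soil_depress[[1L]], soil_scale = rp$soil_scale[[1L]]
  )
  config <- do.call(world_config, cfg)
  covs <- lapply(stats::setNames(nm = model_covariates()), ra)
  layers <- lapply(list(yield = "yield", harvested_area = "harvested_area",
                        country_id = "country_id", continent_id = "continent_id"), ra)
  grids <- c(list(layers$yield, layers$harvested_area), covs)
  for (g in grids[-1L]) stop_if_misaligned(grids[[1L]], g, "world layers")
  truth <- structure(
    list(potential_yield = ra("truth_potential_yield"),
         noise_field = ra("truth_noise_field"),
         response_params = config$response_params),
    class = "truth_record"
  )
  structure(
    list(yield = layers$yield, harvested_area = layers$harvested_area,
         covariates = covs, country_id = layers$country_id,
         continent_id = layers$continent_id,
         daily_temp_C = read_matrix_txt(file.path(dir, "daily_temp_C.txt")),
         daily_precip_mm = read_matrix_txt(file.path(dir, "daily_precip_mm.txt")),
         config = config, truth = truth),
    class = "crop_world"
  )
}

# grid field from per-feature-row values, NA elsewhere
field_from_rows <- function(template, features, values) {
  out <- template
  out$values[] <- NA_real_
  out$values[features$cell] <- values
  out
}

#' Run the full shock-analysis pipeline on a synthetic world
#'
#' Generate -> climate-bin -> feature table -> fit ensemble -> scenario
#' predictions -> production aggregation -> evaluation, writing the result
#' tables (CSV), a run manifest (JSON) and optionally the yield-change maps
#' (ASCII grids) under `out_dir`. Reruns with an identical configuration
#' produce byte-identical tables.
#'
#' @param world_cfg a [world_config()].
#' @param climate a [crop_climate_spec()].
#' @param control a [model_control()].
#' @param scenarios character vector of [scenario_catalogue()] names, or
#'   `"all"` for the full catalogue.
#' @param out_dir output directory; created if needed.
#' @param write_maps also write baseline and per-scenario yield maps.
#' @return (invisibly) list with the in-memory objects (`world`, `bins`,
#'   `features`, `fit`, `global` table, `report`) and `out_dir`.
#' @export
run_pipeline <- function(world_cfg = world_config(),
                         climate = crop_climate_spec(),
                         control = model_control(),
                         scenarios = "all",
                         out_dir = tempfile("agrishock_run_"),
                         write_maps = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  catalogue <- scenario_catalogue()
  if (identical(scenarios, "all")) scenarios <- names(catalogue)
  unknown <- setdiff(scenarios, names(catalogue))
  if (length(unknown)) stop("unknown scenarios: ", paste(unknown, collapse = ", "))

  world <- generate_world(world_cfg)
  bins <- bin_world(world, climate)
  features <- build_feature_table(world, bins)
  fit <- fit_yield_models(features, control)

  area <- world$harvested_area
  baseline_field <- field_from_rows(world$yield, features, fit$baseline_mean)
  baseline_prod <- production(baseline_field, area)
  if (write_maps) write_ascii_grid(baseline_field, file.path(out_dir, "baseline_yield.asc"))

  global_rows <- list()
  country_rows <- list()
  for (nm in scenarios) {
    sc <- catalogue[[nm]]
    pred <- predict(fit, scenario = sc)
    sc_field <- field_from_rows(world$yield, features, pred)
    sc_prod <- production(sc_field, area)
    global_rows[[nm]] <- data.frame(
      scenario = nm, severity = sc$severity,
      global_change_pct = global_change(baseline_prod, sc_prod)
    )
    cc <- country_change(baseline_prod, sc_prod, world$country_id)
    cc$scenario <- nm
    country_rows[[nm]] <- cc
    if (write_maps) {
      write_ascii_grid(yield_change(baseline_field, sc_field),
                       file.path(out_dir, paste0("yield_change_", nm, ".asc")))
    }
  }
  global_tab <- do.call(rbind, global_rows)
  rownames(global_tab) <- NULL
  country_tab <- do.call(rbind, country_rows)
  rownames(country_tab) <- NULL

  report <- evaluate_ensemble(fit, world)

  utils::write.csv(global_tab, file.path(out_dir, "global_change.csv"), row.names = FALSE)
  utils::write.csv(country_tab, file.path(out_dir, "country_change.csv"), row.names = FALSE)
  utils::write.csv(report$per_bin, file.path(out_dir, "bin_performance.csv"), row.names = FALSE)

  manifest <- list(
    package_version = as.character(utils::packageVersion("agrishock")),
    seed = world_cfg$seed,
    model_seed = control$seed,
    grid = c(world_cfg$grid_rows, world_cfg$grid_cols),
    n_iterations = control$n_iterations,
    n_trees = control$n_trees,
    scenarios = scenarios,
    outputs = c("global_change.csv", "country_change.csv", "bin_performance.csv")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(world = world, bins = bins, features = features, fit = fit,
                 global = global_tab, country = country_tab, report = report,
                 out_dir = out_dir))
}
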