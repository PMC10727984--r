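# shared fixtures, built once per test run and cached

.fixtures <- new.env(parent = emptyenv())

# small world for unit tests: 30x30 cells, 2 years of daily climate
tiny_world <- function(seed = 7) {
  key <- paste0("tiny_", seed)
  if (is.null(.fixtures[[key]])) {
    .fixtures[[key]] <- generate_world(
      world_config(grid_rows = 30, grid_cols = 30, n_years = 2, seed = seed)
    )
  }
  .fixtures[[key]]
}

tiny_features <- function(seed = 7) {
  key <- paste0("tinyft_", seed)
  if (is.null(.fixtures[[key]])) {
    w <- tiny_world(seed)
    .fixtures[[key]] <- build_feature_table(w, bin_world(w))
  }
  .fixtures[[key]]
}

# the full study-condition run shared by the recovery/scenario/uncertainty
# checks: default 50x50 world, 25 iterations at a reduced forest size
study_run <- function() {
  if (is.null(.fixtures$study)) {
    w <- generate_world(world_config(seed = 1))
    bins <- bin_world(w)
    features <- build_feature_table(w, bins)
    fit <- suppressWarnings(fit_yield_models(
      features, model_control(n_trees = 200, n_iterations = 25, seed = 1)
    ))
    .fixtures$study <- list(world = w, bins = bins, features = features, fit = fit)
  }
  .fixtures$study
}

# naive per-day accumulation oracle for growing degree days
gdd_loop_oracle <- function(temps, base, cutoff, days_per_year = 365L) {
  n_years <- length(temps) %/% days_per_year
  ann <- numeric(n_years)
  for (y in seq_len(n_years)) {
    acc <- 0
    for (d in seq_len(days_per_year)) {
      t_d <- temps[(y - 1L) * days_per_year + d]
      if (t_d > base) acc <- acc + min(t_d, cutoff) - base
    }
    ann[y] <- acc
  }
  mean(ann)
}
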