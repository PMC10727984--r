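#' Random-forest ensemble control parameters
#'
#' Defaults follow common random-forest practice for this kind of yield
#' modelling: 1,000 trees, terminal nodes of at least 5 observations, 2
#' candidate split variables, 12 x 12-cell (one-degree at 5 arcmin) spatial
#' blocks split 75/25 into training and testing, repeated over 25 iterations.
#'
#' @param n_trees trees per forest.
#' @param min_leaf_size minimum observations in a terminal node.
#' @param n_split_vars candidate variables per split (mtry).
#' @param block_size_cells side of the square spatial blocks, in grid cells.
#' @param train_fraction fraction of blocks assigned to training;
#'   `floor(train_fraction * n_blocks)` blocks train, the rest test.
#' @param n_iterations independent split/fit repetitions.
#' @param min_bin_rows bins with fewer training rows are skipped (warning).
#' @param seed master seed; per-iteration and per-forest seeds are derived
#'   from it deterministically.
#' @return a `model_control` list.
#' @export
model_control <- function(n_trees = 1000L, min_leaf_size = 5L, n_split_vars = 2L,
                          block_size_cells = 12L, train_fraction = 0.75,
                          n_iterations = 25L, min_bin_rows = 50L, seed = 1L) {
  stopifnot(n_trees >= 1, min_leaf_size >= 1, n_split_vars >= 1,
            block_size_cells >= 1, train_fraction > 0, train_fraction < 1,
            n_iterations >= 1, min_bin_rows >= 1)
  structure(
    list(n_trees = as.integer(n_trees), min_leaf_size = as.integer(min_leaf_size),
         n_split_vars = as.integer(n_split_vars),
         block_size_cells = as.integer(block_size_cells),
         train_fraction = train_fraction, n_iterations = as.integer(n_iterations),
         min_bin_rows = as.integer(min_bin_rows), seed = as.integer(seed)),
    class = "model_control"
  )
}

# block id of each feature row from its grid position
block_ids <- function(features, block_size) {
  br <- (features$row - 1L) %/% block_size
  bc <- (features$col - 1L) %/% block_size
  br * (max(bc) + 1L) + bc + 1L
}

#' Spatially blocked train/test split
#'
#' Imposes a coarse grid of `block_size_cells`-sided square blocks (ragged at
#' the edges) over the cell grid and assigns whole blocks to training or
#' testing, so no block ever contributes cells to both sets and spatial
#' autocorrelation cannot leak across the split.
#'
#' @param features feature table from [build_feature_table()].
#' @param control a [model_control()].
#' @param seed seed for the block permutation.
#' @return list with `train` (logical per row), `block_id` (integer per row),
#'   and `train_blocks` / `test_blocks` (block ids).
#' @export
spatial_block_split <- function(features, control = model_control(), seed = control$seed) {
  bid <- block_ids(features, control$block_size_cells)
  blocks <- sort(unique(bid))
  if (length(blocks) < 2L) stop("need at least 2 non-empty spatial blocks to split")
  n_train <- max(1L, floor(control$train_fraction * length(blocks)))
  if (n_train >= length(blocks)) n_train <- length(blocks) - 1L
  set.seed(seed)
  train_blocks <- sort(sample(blocks, n_train))
  list(train = bid %in% train_blocks, block_id = bid,
       train_blocks = train_blocks, test_blocks = setdiff(blocks, train_blocks))
}

# one forest on one climate bin's training rows
train_bin_model <- function(train_df, control, seed) {
  ranger::ranger(
    y = train_df$yield, x = train_df[, model_covariates(), drop = FALSE],
    num.trees = control$n_trees,
    mtry = min(control$n_split_vars, length(model_covariates())),
    min.node.size = control$min_leaf_size,
    seed = seed, num.threads = 1L
  )
}

#' Fit the per-climate-bin yield-model ensemble
#'
#' For each iteration: draw a fresh spatially blocked train/test split, fit
#' one random-forest regressor per climate bin on the training rows (yield on
#' the model covariates), record held-out Nash-Sutcliffe efficiency and RMSE
#' per bin, and predict baseline yield for every cropland cell. Bins with
#' fewer training rows than `min_bin_rows` are skipped with a warning and
#' carry NA predictions.
#'
#' @param features feature table from [build_feature_table()].
#' @param control a [model_control()].
#' @return an object of class `yield_ensemble` with methods `print`,
#'   `summary`, `predict`, `fitted`, `residuals` and `plot`. Elements:
#'   `features`, `control`, `iterations` (per iteration: `split`, `models`
#'   keyed by bin, `baseline` predictions per row, `metrics` data.frame),
#'   `baseline_mean` (across-iteration mean prediction per row).
#' @export
fit_yield_models <- function(features, control = model_control()) {
  stopifnot(is.data.frame(features), inherits(control, "model_control"))
  bins <- sort(unique(features$bin_id))
  set.seed(control$seed)
  iter_seeds <- sample.int(2147400000L, control$n_iterations)
  skipped <- character(0)

  iterations <- vector("list", control$n_iterations)
  for (it in seq_len(control$n_iterations)) {
    split <- spatial_block_split(features, control, seed = iter_seeds[it])
    baseline <- rep(NA_real_, nrow(features))
    models <- list()
    metrics <- data.frame(bin_id = integer(), n_train = integer(),
                          n_test = integer(), nse = double(), rmse = double())
    for (b in bins) {
      in_bin <- features$bin_id == b
      tr <- in_bin & split$train
      te <- in_bin & !split$train
      if (sum(tr) < control$min_bin_rows) {
        skipped <- union(skipped, sprintf("iteration %d bin %d (%d rows)", it, b, sum(tr)))
        next
      }
      fit <- train_bin_model(features[tr, , drop = FALSE], control,
                             seed = iter_seeds[it] + b)
      models[[as.character(b)]] <- fit
      baseline[in_bin] <- predict_forest(fit, features[in_bin, , drop = FALSE])
      # NSE needs a test sample large enough for its variance denominator to
      # be meaningful; undersized test sets keep RMSE but no NSE
      bin_nse <- bin_rmse <- NA_real_
      if (sum(te) >= 2L) {
        pred_te <- baseline[which(te)]
        obs_te <- features$yield[te]
        if (sum(te) >= 10L && stats::var(obs_te) > 0) bin_nse <- nse(obs_te, pred_te)
        bin_rmse <- sqrt(mean((obs_te - pred_te)^2))
      }
      metrics <- rbind(metrics, data.frame(
        bin_id = b, n_train = sum(tr), n_test = sum(te),
        nse = bin_nse, rmse = bin_rmse
      ))
    }
    iterations[[it]] <- list(split = split, models = models,
                             baseline = baseline, metrics = metrics)
  }
  if (length(skipped)) {
    warning(sprintf("%d bin fits skipped for too few training rows (first: %s)",
                    length(skipped), skipped[[1L]]), call. = FALSE)
  }
  base_mat <- vapply(iterations, `[[`, numeric(nrow(features)), "baseline")
  # mean over the iterations in which the cell's bin had a model
  base_mean <- rowMeans(base_mat, na.rm = TRUE)
  base_mean[is.nan(base_mean)] <- NA_real_
  structure(
    list(features = features, control = control, iterations = iterations,
         baseline_mean = base_mean, bins = bins,
         skipped = skipped),
    class = "yield_ensemble"
  )
}

predict_forest <- function(fit, newdata) {
  stats::predict(fit, data = newdata[, model_covariates(), drop = FALSE],
                 num.threads = 1L)$predictions
}

#' Predict yields from a fitted ensemble, optionally under a shock scenario
#'
#' Applies each iteration's per-bin forests to the (possibly shocked) feature
#' table. Scenario predictions reuse the baseline forests — no refitting under
#' shock — so a severity-0 scenario reproduces the baseline predictions
#' exactly.
#'
#' @param object a `yield_ensemble`.
#' @param scenario optional [shock_scenario()] applied to the stored feature
#'   table before prediction.
#' @param newdata optional replacement feature table (overrides `scenario`).
#' @param type `"mean"` (across-iteration mean, default) or `"iterations"`
#'   (rows x iterations matrix).
#' @param ... unused.
#' @return numeric vector (or matrix) of predicted yield, t/ha, aligned to
#'   the feature-table rows; NA where the cell's bin was skipped.
#' @export
predict.yield_ensemble <- function(object, scenario = NULL, newdata = NULL,
                                   type = c("mean", "iterations"), ...) {
  type <- match.arg(type)
  feats <- if (!is.null(newdata)) {
    newdata
  } else if (!is.null(scenario)) {
    apply_shock(object$features, scenario)
  } else {
    object$features
  }
  n <- nrow(feats)
  out <- matrix(NA_real_, n, length(object$iterations))
  for (it in seq_along(object$iterations)) {
    models <- object$iterations[[it]]$models
    for (b in names(models)) {
      in_bin <- feats$bin_id == as.integer(b)
      if (!any(in_bin)) next
      out[in_bin, it] <- predict_forest(models[[b]], feats[in_bin, , drop = FALSE])
    }
  }
  if (type == "iterations") return(out)
  m <- rowMeans(out, na.rm = TRUE)
  m[is.nan(m)] <- NA_real_
  m
}

#' @export
fitted.yield_ensemble <- function(object, ...) object$baseline_mean

#' @export
residuals.yield_ensemble <- function(object, ...) {
  object$features$yield - object$baseline_mean
}

#' @export
print.yield_ensemble <- function(x, ...) {
  cat(sprintf("<yield_ensemble> %d climate bins, %d iterations, %d trees/forest\n",
              length(x$bins), x$control$n_iterations, x$control$n_trees))
  cat(sprintf("  %d cropland cells; %d bin fits skipped\n",
              nrow(x$features), length(x$skipped)))
  invisible(x)
}

#' Summarize held-out performance of a fitted ensemble
#'
#' Two held-out NSE estimators are reported per bin: `pooled_nse` pools every
#' iteration's test pairs into one score (the headline measure — stable even
#' when single-iteration test sets are small), and `mean_nse`, the mean of
#' the per-iteration scores. The performance class uses the pooled score.
#'
#' @param object a `yield_ensemble`.
#' @param ... unused.
#' @return a `summary.yield_ensemble`: per-bin table of pooled and
#'   mean-over-iteration held-out NSE, mean RMSE, and the performance class,
#'   plus the share of bins in each class.
#' @export
summary.yield_ensemble <- function(object, ...) {
  feats <- object$features
  all_metrics <- do.call(rbind, lapply(object$iterations, `[[`, "metrics"))
  pooled_nse_of <- function(b) {
    obs <- c(); pred <- c()
    for (it in object$iterations) {
      te <- which(feats$bin_id == b & !it$split$train)
      pr <- it$baseline[te]
      ok <- !is.na(pr)
      obs <- c(obs, feats$yield[te][ok]); pred <- c(pred, pr[ok])
    }
    if (length(obs) < 10L || stats::var(obs) == 0) NA_real_ else nse(obs, pred)
  }
  per_bin <- do.call(rbind, lapply(split(all_metrics, all_metrics$bin_id), function(d) {
    data.frame(bin_id = d$bin_id[[1L]],
               n_iterations = nrow(d),
               pooled_nse = pooled_nse_of(d$bin_id[[1L]]),
               mean_nse = mean(d$nse, na.rm = TRUE),
               mean_rmse = mean(d$rmse, na.rm = TRUE))
  }))
  rownames(per_bin) <- NULL
  per_bin$class <- vapply(per_bin$pooled_nse, classify_performance, "")
  structure(list(per_bin = per_bin,
                 class_share = table(factor(per_bin$class,
                                            levels = c("very good", "good", "below")))),
            class = "summary.yield_ensemble")
}

#' @export
print.summary.yield_ensemble <- function(x, ...) {
  cat("Held-out performance by climate bin (mean over iterations):\n")
  print(x$per_bin, digits = 3)
  sh <- x$class_share / max(sum(x$class_share), 1L)
  cat(sprintf("\nvery good (NSE > 0.75): %.0f%%   good (0.65-0.75]: %.0f%%   below: %.0f%%\n",
              100 * sh[["very good"]], 100 * sh[["good"]], 100 * sh[["below"]]))
  invisible(x)
}

#' Observed versus predicted baseline yields
#'
#' @param x a `yield_ensemble`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.yield_ensemble <- function(x, ...) {
  ok <- !is.na(x$baseline_mean)
  graphics::plot(x$features$yield[ok], x$baseline_mean[ok],
                 xlab = "observed yield (t/ha)",
                 ylab = "predicted baseline yield (t/ha)",
                 pch = 16, cex = 0.4, col = "#00000055", ...)
  graphics::abline(0, 1, col = "red")
  invisible(x)
}
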