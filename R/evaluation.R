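#' Nash-Sutcliffe efficiency
#'
#' `1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)`: 1 is a perfect
#' prediction, 0 matches the constant-mean predictor, negative is worse than
#' it.
#'
#' @param observed,predicted paired numeric vectors, at least 2 pairs.
#' @return scalar NSE (<= 1).
#' @export
nse <- function(observed, predicted) {
  if (length(observed) != length(predicted)) stop("length mismatch")
  if (length(observed) < 2L) stop("need at least 2 pairs")
  denom <- sum((observed - mean(observed))^2)
  if (denom == 0) stop("NSE undefined: observations are constant")
  1 - sum((observed - predicted)^2) / denom
}

#' Classify an NSE score
#'
#' @param nse_value finite NSE.
#' @return `"very good"` (NSE > 0.75), `"good"` (0.65 < NSE <= 0.75), or
#'   `"below"`.
#' @export
classify_performance <- function(nse_value) {
  if (!is.finite(nse_value)) return("below")
  if (nse_value > 0.75) "very good" else if (nse_value > 0.65) "good" else "below"
}

#' Production-weighted country-level coefficient of determination
#'
#' Weighted R-squared of modelled against reference country yields with
#' production weights: `1 - sum(w e^2) / sum(w (ref - wmean(ref))^2)` with
#' `e = ref - modelled`. Used to validate baseline country yields against an
#' independent reference (on synthetic worlds, the generator's noise-free
#' country means).
#'
#' @param modelled,reference country-level yields, t/ha.
#' @param weights production weights, t; nonnegative, at least 3 countries
#'   with positive weight.
#' @return scalar weighted R-squared.
#' @export
weighted_country_r2 <- function(modelled, reference, weights) {
  stopifnot(length(modelled) == length(reference),
            length(weights) == length(reference))
  if (any(weights < 0)) stop("weights must be nonnegative")
  pos <- weights > 0
  if (sum(pos) < 3L) stop("need at least 3 countries with positive weight")
  w <- weights[pos]; m <- modelled[pos]; r <- reference[pos]
  wmean <- sum(w * r) / sum(w)
  denom <- sum(w * (r - wmean)^2)
  if (denom == 0) stop("weighted R2 undefined: reference has no weighted variance")
  1 - sum(w * (r - m)^2) / denom
}

#' Per-cell coefficient of variation of predictions across iterations
#'
#' The pipeline's uncertainty measure: sample standard deviation divided by
#' mean of each cell's baseline predictions over the repeated train/test
#' iterations.
#'
#' @param pred_matrix cells x iterations prediction matrix (>= 2 iterations);
#'   iterations in which a cell's bin had no model may be NA.
#' @return numeric vector of per-cell CV (sample sd over non-missing
#'   iterations / their mean); NA where fewer than 2 iterations are available
#'   or the mean is 0.
#' @export
prediction_cv <- function(pred_matrix) {
  stopifnot(is.matrix(pred_matrix), ncol(pred_matrix) >= 2L)
  n_ok <- rowSums(!is.na(pred_matrix))
  m <- rowMeans(pred_matrix, na.rm = TRUE)
  s <- apply(pred_matrix, 1L, stats::sd, na.rm = TRUE)
  ifelse(n_ok < 2L | is.na(m) | m == 0, NA_real_, s / m)
}

#' Evaluation report for a fitted ensemble on a synthetic world
#'
#' Bundles the held-out per-bin metrics, the production-weighted country
#' validation against the generator's noise-free truth, and the per-cell
#' prediction CV.
#'
#' @param fit a `yield_ensemble`.
#' @param world the `crop_world` the features came from.
#' @return list: `per_bin` (mean NSE/RMSE and class), `country_r2`,
#'   `cv` (per-row CV vector), `median_cv`.
#' @export
evaluate_ensemble <- function(fit, world) {
  stopifnot(inherits(fit, "yield_ensemble"), inherits(world, "crop_world"))
  sm <- summary(fit)
  pred_mat <- vapply(fit$iterations, `[[`,
                     numeric(nrow(fit$features)), "baseline")
  cv <- prediction_cv(pred_mat)

  # reference: noise-free true yield, averaged per country; weights: modelled production
  feats <- fit$features
  truth_y <- true_yield(world$covariates, world$truth$potential_yield,
                        world$truth$response_params)$values[feats$cell]
  ok <- !is.na(fit$baseline_mean)
  ctry <- feats$country_id[ok]
  modelled <- tapply(fit$baseline_mean[ok], ctry, mean)
  reference <- tapply(truth_y[ok], ctry, mean)
  weights <- tapply(fit$baseline_mean[ok] * feats$harvested_area[ok], ctry, sum)
  r2 <- weighted_country_r2(as.numeric(modelled), as.numeric(reference),
                            as.numeric(weights))
  list(per_bin = sm$per_bin, country_r2 = r2, cv = cv,
       median_cv = stats::median(cv, na.rm = TRUE))
}
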