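#' Define an input-shock scenario
#'
#' A scenario reduces a subset of the shockable covariates by a common
#' severity; everything else (non-mineral fertilizer, labour, irrigation,
#' soils) is frozen at baseline.
#'
#' @param name scenario label.
#' @param shocked_covariates character subset of [shockable_covariates()].
#' @param severity fractional reduction in `[0, 1]` (0.25/0.50/0.75 in the
#'   standard catalogue; 1 = input removed entirely).
#' @return a `shock_scenario` list.
#' @export
shock_scenario <- function(name, shocked_covariates, severity) {
  bad <- setdiff(shocked_covariates, shockable_covariates())
  if (length(bad)) {
    stop("not shockable (frozen or unknown): ", paste(bad, collapse = ", "))
  }
  if (severity < 0 || severity > 1) stop("severity must lie in [0, 1]")
  structure(list(name = name,
                 shocked_covariates = unique(shocked_covariates),
                 severity = severity),
            class = "shock_scenario")
}

#' @export
print.shock_scenario <- function(x, ...) {
  cat(sprintf("<shock_scenario> %s: %.0f%% reduction of {%s}\n",
              x$name, 100 * x$severity,
              paste(x$shocked_covariates, collapse = ", ")))
  invisible(x)
}

#' The standard scenario catalogue
#'
#' Seven scenario families — N, P, K, machinery, pesticide (all four groups
#' together), all fertilizers (N+P+K), and all inputs — each at 25%, 50% and
#' 75% severity, plus the control run in which every shockable input is set
#' to zero (severity 1).
#'
#' @return named list of 22 [shock_scenario()]s; the control is named
#'   `"control"`, the rest `"<family>_<severity>"` (e.g. `"all_inputs_50"`).
#' @export
scenario_catalogue <- function() {
  pest <- c("pest_herbicide", "pest_insecticide", "pest_fungicide", "pest_other")
  families <- list(
    n = "n_rate", p = "p_rate", k = "k_rate",
    machinery = "machinery", pesticide = pest,
    fertilizer = c("n_rate", "p_rate", "k_rate"),
    all_inputs = shockable_covariates()
  )
  out <- list()
  for (fam in names(families)) {
    for (sev in c(0.25, 0.50, 0.75)) {
      nm <- sprintf("%s_%d", fam, as.integer(100 * sev))
      out[[nm]] <- shock_scenario(nm, families[[fam]], sev)
    }
  }
  out$control <- shock_scenario("control", shockable_covariates(), 1)
  out
}

#' Apply a shock scenario to a feature table
#'
#' Multiplies the scenario's shocked covariate columns by `(1 - severity)`;
#' every other column is returned bit-identical.
#'
#' @param features feature table from [build_feature_table()].
#' @param scenario a [shock_scenario()].
#' @return the shocked feature table.
#' @export
apply_shock <- function(features, scenario) {
  stopifnot(inherits(scenario, "shock_scenario"))
  missing <- setdiff(scenario$shocked_covariates, names(features))
  if (length(missing)) {
    stop("covariates absent from feature table: ", paste(missing, collapse = ", "))
  }
  for (nm in scenario$shocked_covariates) {
    features[[nm]] <- features[[nm]] * (1 - scenario$severity)
  }
  features
}

#' Relative yield change of a scenario against baseline
#'
#' @param baseline,scenario aligned yield [grid_field()]s.
#' @param decreases_only if TRUE, cells where the scenario yield rose are
#'   masked out (NA), matching map products that display losses only.
#' @return [grid_field()] of `(scenario - baseline) / baseline`; NA where the
#'   baseline is 0 or missing.
#' @export
yield_change <- function(baseline, scenario, decreases_only = FALSE) {
  stop_if_misaligned(baseline, scenario, "yield fields")
  b <- baseline$values; s <- scenario$values
  ch <- ifelse(is.na(b) | is.na(s) | b == 0, NA_real_, (s - b) / b)
  if (decreases_only) ch[!is.na(ch) & ch > 0] <- NA_real_
  out <- baseline
  out$values <- ch
  out
}
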