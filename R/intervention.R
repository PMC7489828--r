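# Counterfactual determinant-improvement scenarios: scale determinant values
# up or down, re-predict the tract difference with a fitted model while
# preserving each tract's residual, and count the tracts/population left in
# excess risk.

#' Define a counterfactual intervention scenario
#'
#' @param magnitude positive fraction, e.g. 0.10 or 0.20 for a 10% or 20%
#'   improvement.
#' @param directions named character vector mapping each modified determinant
#'   to `"increase"` or `"decrease"`.
#' @param caps named list mapping determinants to `c(floor, ceiling)` clamp
#'   ranges applied after scaling (e.g. `c(0, 100)` for percentages).
#' @param special_rules list of rules, each a list with `determinant`,
#'   `threshold` and `set_to`: after scaling, values at or above `threshold`
#'   are set to `set_to` (e.g. high-school graduation at 90% or higher is
#'   raised to 100%).
#' @return object of class `intervention_scenario`.
#' @export
intervention_scenario <- function(magnitude, directions, caps = list(),
                                  special_rules = list()) {
  if (length(magnitude) != 1L || !is.finite(magnitude) || magnitude <= 0) {
    abort_config("`magnitude` must be a single positive fraction")
  }
  if (length(directions) == 0 || is.null(names(directions)) ||
      !all(directions %in% c("increase", "decrease"))) {
    abort_config("`directions` must be a named vector of increase/decrease")
  }
  for (r in special_rules) {
    if (!all(c("determinant", "threshold", "set_to") %in% names(r))) {
      abort_config("each special rule needs determinant, threshold, set_to")
    }
  }
  structure(list(magnitude = magnitude, directions = directions,
                 caps = caps, special_rules = special_rules),
            class = "intervention_scenario")
}

#' The standard determinant-improvement scenario
#'
#' Mirrors the canonical intervention: raise the percentage of high-school
#' graduates and the median household income, lower the percentages of
#' households receiving food stamps, without jobs, and with diabetes,
#' hypertension or hyperlipidemia, all by the given relative magnitude;
#' percentage columns are clamped to \[0, 100\] and high-school graduation at
#' 90% or above is raised to 100%.
#'
#' @param magnitude relative improvement (default 0.10).
#' @return an [intervention_scenario()].
#' @export
improvement_scenario <- function(magnitude = 0.10) {
  pct <- c("pct_hs_grad", "pct_food_stamps", "pct_no_jobs",
           "pct_diabetes", "pct_hypertension", "pct_hyperlipidemia")
  intervention_scenario(
    magnitude = magnitude,
    directions = c(pct_hs_grad = "increase", median_income = "increase",
                   pct_food_stamps = "decrease", pct_no_jobs = "decrease",
                   pct_diabetes = "decrease", pct_hypertension = "decrease",
                   pct_hyperlipidemia = "decrease"),
    caps = stats::setNames(rep(list(c(0, 100)), length(pct)), pct),
    special_rules = list(list(determinant = "pct_hs_grad",
                              threshold = 90, set_to = 100)))
}

#' Apply a scenario to a determinant table
#'
#' Relative mode (default) multiplies increased determinants by
#' `1 + magnitude` and decreased ones by `1 - magnitude`; absolute mode adds
#' or subtracts `magnitude` units (percentage points). Caps clamp the scaled
#' values; special rules run last on the scaled values.
#'
#' @param determinants determinant table.
#' @param scenario an [intervention_scenario()].
#' @param mode `"relative"` (default) or `"absolute"`.
#' @return the modified determinant table (untouched columns identical).
#' @export
#' @examples
#' d <- data.frame(tract_id = "T1", median_income = 50000)
#' s <- intervention_scenario(0.10, c(median_income = "increase"))
#' apply_scenario(d, s)$median_income  # 55000
apply_scenario <- function(determinants, scenario,
                           mode = c("relative", "absolute")) {
  mode <- match.arg(mode)
  stopifnot(inherits(scenario, "intervention_scenario"))
  unknown <- setdiff(names(scenario$directions), names(determinants))
  if (length(unknown) > 0) {
    abort_config(sprintf("scenario directs unknown determinant(s): %s",
                         paste(unknown, collapse = ", ")))
  }
  out <- determinants
  for (d in names(scenario$directions)) {
    sgn <- if (scenario$directions[[d]] == "increase") 1 else -1
    x <- out[[d]]
    x <- if (mode == "relative") {
      x * (1 + sgn * scenario$magnitude)
    } else {
      x + sgn * scenario$magnitude
    }
    cap <- scenario$caps[[d]]
    if (!is.null(cap)) x <- pmin(pmax(x, cap[1]), cap[2])
    out[[d]] <- x
  }
  for (r in scenario$special_rules) {
    d <- r$determinant
    if (!d %in% names(out)) {
      abort_config(sprintf("special rule targets unknown determinant `%s`", d))
    }
    out[[d]] <- ifelse(out[[d]] >= r$threshold, r$set_to, out[[d]])
  }
  out
}

#' Predict the tract difference under modified determinants
#'
#' Residual-preserving (delta-method) counterfactual: each tract's predicted
#' difference is its baseline difference shifted by
#' `sum_j beta_j (x'_j - x_j)` over the fitted model's terms, so the part of
#' the baseline difference the model does not explain persists unchanged.
#'
#' @param fit a [multivariate_fit()] result.
#' @param summary baseline `tract_risk_summary`.
#' @param baseline baseline determinant table.
#' @param modified modified determinant table (e.g. from [apply_scenario()]).
#' @return data frame `tract_id`, `predicted_difference`.
#' @export
predict_difference <- function(fit, summary, baseline, modified) {
  stopifnot(inherits(fit, "regression_result"))
  terms <- fit$terms$name
  for (tbl in list(baseline, modified)) {
    missing_terms <- setdiff(terms, names(tbl))
    if (length(missing_terms) > 0) {
      abort_data(sprintf("model term(s) missing from determinant table: %s",
                         paste(missing_terms, collapse = ", ")))
    }
  }
  ids <- summary$tract_id
  b <- baseline[match(ids, baseline$tract_id), , drop = FALSE]
  m <- modified[match(ids, modified$tract_id), , drop = FALSE]
  if (any(is.na(b$tract_id)) || any(is.na(m$tract_id))) {
    abort_data("determinant tables do not cover every summary tract")
  }
  shift <- rep(0, length(ids))
  for (i in seq_along(terms)) {
    shift <- shift + fit$terms$slope[i] * (m[[terms[i]]] - b[[terms[i]]])
  }
  data.frame(tract_id = ids,
             predicted_difference = summary$difference_per_100k + shift,
             stringsAsFactors = FALSE)
}

#' Summarize a counterfactual scenario
#'
#' Counts tracts whose predicted difference is strictly negative (observed
#' risk would still exceed expected), the population they hold, and that
#' population's share of the total.
#'
#' @param predicted data frame from [predict_difference()].
#' @param summary baseline `tract_risk_summary` supplying populations
#'   (or any data frame with `tract_id` and `population`).
#' @return object of class `scenario_result`: list with `n_negative_tracts`,
#'   `negative_tract_population`, `total_population`,
#'   `share_of_total_population` and `per_tract`.
#' @export
summarize_scenario <- function(predicted, summary) {
  m <- merge(predicted, as.data.frame(summary)[, c("tract_id", "population")],
             by = "tract_id", sort = TRUE)
  if (nrow(m) != nrow(predicted)) {
    abort_data("predictions and populations do not align on tract_id")
  }
  neg <- m$predicted_difference < 0
  structure(list(
    n_negative_tracts = sum(neg),
    negative_tract_population = sum(m$population[neg]),
    total_population = sum(m$population),
    share_of_total_population = sum(m$population[neg]) / sum(m$population),
    per_tract = m), class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf(
    "Scenario: %d tract(s) with negative difference, population %d (%.0f%% of total)\n",
    x$n_negative_tracts, x$negative_tract_population,
    100 * x$share_of_total_population))
  invisible(x)
}
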