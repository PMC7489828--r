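# Observed tract risk via direct age standardization, the expected-minus-
# observed difference per 100 000 (negative = more deaths than the
# individual-level model predicts), and the calibration regression of
# observed on expected risk.

#' US 2000 standard population weights over the 18 five-year bands
#'
#' The conventional standard-million age distribution used for direct age
#' standardization of US mortality rates, collapsed to the package's 18
#' bands and normalized to sum to 1.
#'
#' @return named numeric vector over [age_bands()].
#' @export
us2000_standard <- function() {
  w <- c(0.069135, 0.072533, 0.073032, 0.072169, 0.066478, 0.064530,
         0.071044, 0.080762, 0.081851, 0.072118, 0.062716, 0.048454,
         0.038793, 0.034264, 0.031773, 0.026999, 0.017842, 0.015508)
  names(w) <- age_bands()
  w / sum(w)
}

#' Directly age-standardized death rate per 100 000
#'
#' `100000 * sum_b w_b * deaths_b / pop_b` over age bands, with the standard
#' weights renormalized to the bands that have population (so a tract with an
#' empty band keeps the standardization identity: equal band-specific rates
#' yield that common rate). Deaths in a zero-population band are a data
#' error. The rate is a period rate over the full observation window.
#'
#' @param deaths_by_band named numeric vector of death counts per band.
#' @param population_by_band named numeric vector of band populations.
#' @param standard standard weights (default [us2000_standard()]).
#' @return rate per 100 000 persons over the observation period.
#' @export
#' @examples
#' age_adjusted_rate(c(a = 1, b = 2), c(a = 100, b = 100), c(a = .5, b = .5))
age_adjusted_rate <- function(deaths_by_band, population_by_band,
                              standard = us2000_standard()) {
  bands <- names(deaths_by_band)
  if (is.null(bands) || is.null(names(population_by_band)) ||
      is.null(names(standard))) {
    abort_arg("deaths, populations and standard weights must be named by band")
  }
  if (!all(bands %in% names(population_by_band)) ||
      !all(bands %in% names(standard))) {
    abort_arg("band labels must align across deaths, population and standard")
  }
  pop <- population_by_band[bands]
  w <- standard[bands]
  if (any(deaths_by_band < 0) || any(pop < 0)) {
    abort_arg("deaths and populations must be nonnegative")
  }
  if (any(deaths_by_band > 0 & pop == 0)) {
    abort_data(sprintf("deaths in zero-population band(s): %s",
                       paste(bands[deaths_by_band > 0 & pop == 0],
                             collapse = ", ")))
  }
  keep <- pop > 0
  if (!any(keep)) return(0)
  w <- w[keep] / sum(w[keep])
  1e5 * sum(w * deaths_by_band[keep] / pop[keep])
}

#' Observed age-standardized rate per tract
#'
#' Convenience wrapper applying [age_adjusted_rate()] tract by tract to a
#' deaths-by-band table and a demographic cell table.
#'
#' @param deaths data frame `tract_id`, `age_band`, `deaths`.
#' @param demographics demographic cell table (`tract_id`, `age_band`,
#'   `sex`, `count`).
#' @param standard standard weights.
#' @return data frame `tract_id`, `observed_per_100k`.
#' @export
observed_tract_rates <- function(deaths, demographics,
                                 standard = us2000_standard()) {
  pop_band <- stats::aggregate(count ~ tract_id + age_band,
                               data = demographics, FUN = sum)
  ids <- unique(deaths$tract_id)
  rate <- vapply(ids, function(tid) {
    d <- deaths[deaths$tract_id == tid, , drop = FALSE]
    p <- pop_band[pop_band$tract_id == tid, , drop = FALSE]
    age_adjusted_rate(stats::setNames(d$deaths, d$age_band),
                      stats::setNames(p$count, p$age_band),
                      standard)
  }, numeric(1))
  data.frame(tract_id = ids, observed_per_100k = as.numeric(rate),
             stringsAsFactors = FALSE)
}

#' Observed deaths implied by a rate and a population
#'
#' `rate_per_100k / 100000 * population` -- the rate-times-population step
#' that converts an age-standardized rate into a tract death burden.
#'
#' @param rate_per_100k nonnegative rate(s) per 100 000.
#' @param population nonnegative population(s).
#' @return expected number of deaths (real-valued).
#' @export
observed_tract_deaths <- function(rate_per_100k, population) {
  if (any(rate_per_100k < 0) || any(population < 0)) {
    abort_arg("rate and population must be nonnegative")
  }
  rate_per_100k / 1e5 * population
}

#' Expected-minus-observed risk difference per tract
#'
#' Joins the expected and observed tables and computes
#' `difference_per_100k = expected_per_100k - observed_per_100k`; negative
#' values mean observed deaths exceed the model's expectation (excess risk).
#' Tracts below `min_population` are excluded (small-population tracts whose
#' observed rates are unstable) and recorded in the `excluded` attribute.
#'
#' @param expected data frame from [expected_tract_risk()].
#' @param observed data frame `tract_id`, `observed_per_100k`.
#' @param min_population exclusion threshold (default 50).
#' @return data frame `tract_id`, `expected_per_100k`, `observed_per_100k`,
#'   `difference_per_100k`, `population`, of class `tract_risk_summary`,
#'   with attributes `stats` (min/max/mean/sd of the difference, count and
#'   population of negative-difference tracts) and `excluded`.
#' @export
risk_difference <- function(expected, observed, min_population = 50) {
  unmatched <- setdiff(expected$tract_id, observed$tract_id)
  if (length(unmatched) > 0) {
    abort_data(sprintf("no observed rate for tract(s): %s",
                       paste(unmatched, collapse = ", ")))
  }
  m <- merge(expected, observed, by = "tract_id", sort = TRUE)
  excluded <- m$tract_id[m$population < min_population]
  if (length(excluded) > 0) {
    message(sprintf("excluding %d tract(s) below population %d",
                    length(excluded), min_population))
    m <- m[m$population >= min_population, , drop = FALSE]
  }
  m$difference_per_100k <- m$expected_per_100k - m$observed_per_100k
  out <- m[, c("tract_id", "expected_per_100k", "observed_per_100k",
               "difference_per_100k", "population")]
  rownames(out) <- NULL
  neg <- out$difference_per_100k < 0
  attr(out, "stats") <- list(
    min = min(out$difference_per_100k), max = max(out$difference_per_100k),
    mean = mean(out$difference_per_100k), sd = stats::sd(out$difference_per_100k),
    n_tracts = nrow(out),
    n_negative = sum(neg),
    negative_population = sum(out$population[neg]),
    total_population = sum(out$population),
    share_negative_population = sum(out$population[neg]) / sum(out$population))
  attr(out, "excluded") <- excluded
  class(out) <- c("tract_risk_summary", "data.frame")
  out
}

#' Calibration regression of observed on expected risk
#'
#' Ordinary least squares of the observed tract rate on the expected tract
#' rate, the standard check that the individual-level risk equation
#' reproduces the observed death burden: a well calibrated model gives a
#' slope near 1 and an intercept near 0.
#'
#' @param summary a `tract_risk_summary` (at least 3 tracts).
#' @param level confidence level for the intervals (default 0.95).
#' @return object of class `calibration_fit`: list with `slope`, `intercept`,
#'   `slope_ci95`, `intercept_ci95`, `r_squared`, `slope_covers_1`,
#'   `intercept_covers_0`, `n`.
#' @export
calibration_regression <- function(summary, level = 0.95) {
  if (nrow(summary) < 3) {
    abort_arg("calibration regression needs at least 3 tracts")
  }
  fit <- stats::lm(observed_per_100k ~ expected_per_100k, data = summary)
  ci <- suppressWarnings(stats::confint(fit, level = level))
  co <- stats::coef(fit)
  structure(list(
    slope = unname(co[2]), intercept = unname(co[1]),
    slope_ci95 = unname(ci[2, ]), intercept_ci95 = unname(ci[1, ]),
    r_squared = suppressWarnings(stats::summary.lm(fit))$r.squared,
    slope_covers_1 = ci[2, 1] <= 1 && 1 <= ci[2, 2],
    intercept_covers_0 = ci[1, 1] <= 0 && 0 <= ci[1, 2],
    n = nrow(summary)),
    class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf("Calibration (observed ~ expected), n = %d tracts\n", x$n))
  cat(sprintf("  slope     %.3f (95%% CI %.3f to %.3f)%s\n",
              x$slope, x$slope_ci95[1], x$slope_ci95[2],
              if (x$slope_covers_1) " [covers 1]" else ""))
  cat(sprintf("  intercept %.3f (95%% CI %.3f to %.3f)%s\n",
              x$intercept, x$intercept_ci95[1], x$intercept_ci95[2],
              if (x$intercept_covers_0) " [covers 0]" else ""))
  cat(sprintf("  R-squared %.3f\n", x$r_squared))
  invisible(x)
}
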