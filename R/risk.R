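# Individual CVD death risk: proportional-hazards survival form
# 1 - S0(sex, age band)^exp(beta' (x - c)), rescaled from the 5-year horizon
# of the risk equation to the 4-year death-certificate window, then summed
# per tract into an expected-risk surface.

#' Construct a CVD death risk model
#'
#' Proportional-hazards survival form: the 5-year death probability is
#' `1 - S0(sex, age band)^exp(sum_j beta_j (x_j - c_j))`, with sex- and
#' age-band-specific baseline survival `S0` and person-level covariates
#' `x_j` centered at `c_j`. Persons aged 18 years or younger always receive
#' risk exactly 0.
#'
#' @param baseline_survival data frame with columns `sex`, `age_band`, `s0`;
#'   every `s0` must lie in (0, 1\].
#' @param coefficients named numeric vector; names must be person covariates
#'   (`smoking`, `diabetes`, `hypertension`, `hyperlipidemia`, `sbp`,
#'   `total_chol`, `hdl`). Flags enter as 0/1.
#' @param centers named numeric centering constants; covariates without an
#'   entry are centered at 0.
#' @param horizon_years risk-equation horizon in years (default 5).
#' @return object of class `risk_model`.
#' @export
risk_model <- function(baseline_survival, coefficients, centers = numeric(0),
                       horizon_years = 5) {
  req <- c("sex", "age_band", "s0")
  if (!all(req %in% names(baseline_survival))) {
    abort_config("`baseline_survival` needs columns sex, age_band, s0")
  }
  if (any(baseline_survival$s0 <= 0 | baseline_survival$s0 > 1)) {
    abort_config("baseline survival values must lie in (0, 1]")
  }
  allowed <- c("smoking", "diabetes", "hypertension", "hyperlipidemia",
               "sbp", "total_chol", "hdl")
  if (length(coefficients) == 0 || is.null(names(coefficients)) ||
      !all(names(coefficients) %in% allowed)) {
    abort_config(sprintf("coefficient names must be among: %s",
                         paste(allowed, collapse = ", ")))
  }
  if (horizon_years <= 0) abort_config("`horizon_years` must be positive")
  structure(list(baseline_survival = baseline_survival,
                 coefficients = coefficients,
                 centers = centers,
                 horizon_years = horizon_years),
            class = "risk_model")
}

#' Default risk model with synthetic coefficients
#'
#' A documented default whose baseline survival declines log-linearly with
#' age (about 9% per year of age on the hazard scale, higher for men) and
#' whose covariates are smoking, diabetes, systolic blood pressure (centered
#' at 122 mm Hg) and total cholesterol (centered at 189 mg/dL). The
#' coefficients are synthetic defaults chosen to give plausible magnitudes
#' and orderings; they are not the published values of any specific risk
#' equation, and users analysing real data should supply their own model
#' via [risk_model()] or [read_risk_model()].
#'
#' @return a `risk_model`.
#' @export
default_risk_model <- function() {
  bands <- age_bands()
  mid <- band_lower(bands) + band_width(bands) / 2
  base <- exp(-9.95 + 0.088 * mid)
  bs <- rbind(
    data.frame(sex = "male", age_band = bands,
               s0 = pmax(1 - pmin(base * 1.3, 0.9), 0.05),
               stringsAsFactors = FALSE),
    data.frame(sex = "female", age_band = bands,
               s0 = pmax(1 - pmin(base * 0.77, 0.9), 0.05),
               stringsAsFactors = FALSE))
  risk_model(
    baseline_survival = bs,
    coefficients = c(smoking = 0.60, diabetes = 0.55,
                     sbp = 0.018, total_chol = 0.0035),
    centers = c(sbp = 122, total_chol = 189),
    horizon_years = 5)
}

#' Five-year CVD death risk per person
#'
#' Evaluates `1 - S0^exp(beta' (x - c))` for each person; persons aged 18
#' years or younger receive exactly 0 regardless of covariates.
#'
#' @param persons person table (vectorized; one risk per row).
#' @param model a [risk_model()].
#' @return numeric vector of probabilities in \[0, 1\].
#' @export
#' @examples
#' m <- default_risk_model()
#' p <- data.frame(age = 15, age_band = "15-19", sex = "male", smoking = TRUE,
#'                 diabetes = TRUE, sbp = 200, total_chol = 300)
#' risk_5yr(p, m)  # 0: under-18 rule
risk_5yr <- function(persons, model) {
  stopifnot(inherits(model, "risk_model"))
  n <- nrow(persons)
  risk <- numeric(n)
  adult <- is_adult(persons)
  if (!any(adult)) return(risk)
  bs <- model$baseline_survival
  key <- paste(persons$sex[adult], persons$age_band[adult])
  s0 <- bs$s0[match(key, paste(bs$sex, bs$age_band))]
  if (any(is.na(s0))) {
    abort_config(sprintf("no baseline survival for stratum: %s",
                         paste(unique(key[is.na(s0)]), collapse = ", ")))
  }
  lp <- numeric(sum(adult))
  for (nm in names(model$coefficients)) {
    x <- persons[[nm]]
    if (is.null(x)) abort_data(sprintf("person covariate `%s` is missing", nm))
    x <- as.numeric(x[adult])
    if (any(is.na(x))) {
      abort_data(sprintf("covariate `%s` has missing values for adults", nm))
    }
    cc <- if (nm %in% names(model$centers)) model$centers[[nm]] else 0
    lp <- lp + model$coefficients[[nm]] * (x - cc)
  }
  risk[adult] <- 1 - s0^exp(lp)
  pmin(pmax(risk, 0), 1)
}

#' Rescale a risk to a different horizon
#'
#' Default is the constant-hazard rescaling `1 - (1 - r)^(target/horizon)`;
#' a simple proportional rescaling `r * target/horizon` is available for
#' comparison. Both agree to first order at small risks.
#'
#' @param r5 probabilities in \[0, 1\] at the model horizon.
#' @param target_years target horizon (default 4, the death-certificate
#'   observation window).
#' @param horizon_years source horizon (default 5).
#' @param method `"hazard"` (default) or `"linear"`.
#' @return rescaled probabilities.
#' @export
#' @examples
#' scale_to_horizon(0.05)  # 1 - 0.95^0.8
scale_to_horizon <- function(r5, target_years = 4, horizon_years = 5,
                             method = c("hazard", "linear")) {
  method <- match.arg(method)
  if (any(!is.finite(r5)) || any(r5 < 0) || any(r5 > 1)) {
    abort_arg("risks must lie in [0, 1]")
  }
  if (target_years <= 0 || horizon_years <= 0) {
    abort_arg("horizons must be positive")
  }
  if (method == "hazard") {
    1 - (1 - r5)^(target_years / horizon_years)
  } else {
    pmin(r5 * target_years / horizon_years, 1)
  }
}

#' Expected tract-level CVD death risk
#'
#' Sums each tract's individual risks rescaled to the target horizon and
#' normalizes by the total tract population (all ages, children included) to
#' a risk per 100 000.
#'
#' @param persons person table with biomarkers imputed.
#' @param model a [risk_model()].
#' @param target_years observation horizon (default 4).
#' @param scaling horizon rescaling method passed to [scale_to_horizon()].
#' @return data frame with columns `tract_id`, `expected_deaths`,
#'   `population`, `expected_per_100k`.
#' @export
expected_tract_risk <- function(persons, model, target_years = 4,
                                scaling = c("hazard", "linear")) {
  scaling <- match.arg(scaling)
  r <- scale_to_horizon(risk_5yr(persons, model),
                        target_years = target_years,
                        horizon_years = model$horizon_years,
                        method = scaling)
  expected <- tapply(r, persons$tract_id, sum)
  population <- tapply(rep(1L, nrow(persons)), persons$tract_id, sum)
  out <- data.frame(tract_id = names(expected),
                    expected_deaths = as.numeric(expected),
                    population = as.integer(population),
                    stringsAsFactors = FALSE)
  zero <- out$population == 0
  if (any(zero)) {
    warning(sprintf("excluding %d tract(s) with zero population", sum(zero)),
            call. = FALSE)
    out <- out[!zero, , drop = FALSE]
  }
  out$expected_per_100k <- 1e5 * out$expected_deaths / out$population
  rownames(out) <- NULL
  out
}

#' Write a risk model as JSON
#' @param model a [risk_model()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_risk_model <- function(model, path) {
  stopifnot(inherits(model, "risk_model"))
  jsonlite::write_json(
    list(baseline_survival = model$baseline_survival,
         coefficients = as.list(model$coefficients),
         centers = as.list(model$centers),
         horizon_years = model$horizon_years),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a risk model JSON written by [write_risk_model()]
#' @param path input path.
#' @return a `risk_model`.
#' @export
read_risk_model <- function(path) {
  if (!file.exists(path)) abort_data(sprintf("file not found: %s", path))
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  risk_model(baseline_survival = as.data.frame(x$baseline_survival),
             coefficients = unlist(x$coefficients),
             centers = unlist(x$centers) %||% numeric(0),
             horizon_years = x$horizon_years)
}
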