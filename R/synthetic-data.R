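# Synthetic input generators. Every pipeline input (tract lattice,
# demographic marginals, survey donor pool, claim counts, determinant tables,
# death counts) can be generated with a known, serialized ground truth so the
# downstream statistics have a recoverable target.

#' Generate a rectangular tract lattice with rook adjacency
#'
#' Stands in for a county's census-tract geography: `n_rows * n_cols` unit
#' square tracts, identified row-major, with rook (edge-sharing) adjacency.
#' The construction is deterministic; `seed` is accepted for interface
#' uniformity with the other generators.
#'
#' @param n_rows,n_cols positive integers; their product must be at least 2.
#' @param seed integer seed (unused; the lattice is deterministic).
#' @return an object of class `tract_set`: a list with elements
#'   `tracts` (data frame: `tract_id`, `row`, `col`), `adjacency` (named list
#'   of neighbor `tract_id` vectors) and `geometry` (named list of closed
#'   polygon rings, 5 x 2 matrices of x/y coordinates).
#' @export
#' @examples
#' tr <- gen_tract_lattice(3, 3, seed = 1)
#' lengths(tr$adjacency)
gen_tract_lattice <- function(n_rows, n_cols, seed = 1L) {
  if (length(n_rows) != 1L || length(n_cols) != 1L ||
      !is.finite(n_rows) || !is.finite(n_cols) ||
      n_rows < 1 || n_cols < 1 || n_rows %% 1 != 0 || n_cols %% 1 != 0) {
    abort_arg("`n_rows` and `n_cols` must be positive integers")
  }
  n <- n_rows * n_cols
  if (n < 2) abort_arg("the lattice must contain at least 2 tracts")
  width <- max(3L, nchar(as.character(n)))
  idx <- seq_len(n)
  row <- (idx - 1L) %/% n_cols + 1L
  col <- (idx - 1L) %% n_cols + 1L
  ids <- sprintf(paste0("T%0", width, "d"), idx)
  adjacency <- vector("list", n)
  names(adjacency) <- ids
  at <- function(r, c) ids[(r - 1L) * n_cols + c]
  for (i in idx) {
    nb <- character(0)
    if (row[i] > 1L) nb <- c(nb, at(row[i] - 1L, col[i]))
    if (row[i] < n_rows) nb <- c(nb, at(row[i] + 1L, col[i]))
    if (col[i] > 1L) nb <- c(nb, at(row[i], col[i] - 1L))
    if (col[i] < n_cols) nb <- c(nb, at(row[i], col[i] + 1L))
    adjacency[[i]] <- nb
  }
  geometry <- lapply(idx, function(i) {
    x0 <- col[i] - 1; y0 <- row[i] - 1
    cbind(x = c(x0, x0 + 1, x0 + 1, x0, x0),
          y = c(y0, y0, y0 + 1, y0 + 1, y0))
  })
  names(geometry) <- ids
  structure(
    list(tracts = data.frame(tract_id = ids, row = row, col = col,
                             stringsAsFactors = FALSE),
         adjacency = adjacency, geometry = geometry),
    class = "tract_set")
}

#' Default age-band weights
#'
#' Population shares of the 18 five-year age bands used as the default
#' demographic marginal; the shape follows a large US county age pyramid
#' (working-age plateau, thinning tail beyond 65).
#'
#' @return named numeric vector over [age_bands()], summing to 1.
#' @export
default_age_band_weights <- function() {
  counts <- c(63016, 67435, 71306, 72376, 75512, 77178, 68702, 71183, 76275,
              89920, 96528, 88166, 70504, 53524, 41771, 41026, 33856, 29822)
  w <- counts / sum(counts)
  names(w) <- age_bands()
  w
}

#' Generate tract demographic marginals
#'
#' Draws each tract's total population from a Poisson with mean `mean_pop`
#' and allocates it multinomially over the 18 age bands and two sexes.
#'
#' @param tracts a `tract_set` from [gen_tract_lattice()].
#' @param mean_pop positive mean tract population (Poisson mean). The default
#'   3414 is a typical county-average tract size.
#' @param age_band_weights simplex over the 18 bands (sums to 1 within 1e-9).
#' @param pct_male fraction of males.
#' @param seed integer seed.
#' @return data frame with columns `tract_id`, `age_band`, `sex`, `count`
#'   (one row per tract x band x sex cell).
#' @export
gen_demographics <- function(tracts, mean_pop = 3414,
                             age_band_weights = default_age_band_weights(),
                             pct_male = 0.476, seed = 1L) {
  stopifnot(inherits(tracts, "tract_set"))
  if (length(mean_pop) != 1L || !is.finite(mean_pop) || mean_pop <= 0) {
    abort_arg("`mean_pop` must be a single positive number")
  }
  if (length(age_band_weights) != 18L || any(age_band_weights < 0) ||
      abs(sum(age_band_weights) - 1) > 1e-9) {
    abort_arg("`age_band_weights` must be 18 nonnegative weights summing to 1")
  }
  if (pct_male < 0 || pct_male > 1) abort_arg("`pct_male` must be in [0, 1]")
  ids <- tracts$tracts$tract_id
  bands <- age_bands()
  cellp <- as.vector(outer(age_band_weights, c(pct_male, 1 - pct_male)))
  with_seed(seed, {
    totals <- stats::rpois(length(ids), mean_pop)
    counts <- vapply(totals, function(tt) {
      as.vector(stats::rmultinom(1, tt, cellp))
    }, numeric(36L))
  })
  data.frame(
    tract_id = rep(ids, each = 36L),
    age_band = rep(rep(bands, times = 2L), times = length(ids)),
    sex = rep(rep(c("male", "female"), each = 18L), times = length(ids)),
    count = as.integer(counts),
    stringsAsFactors = FALSE)
}

#' Generate a survey donor pool
#'
#' Emulates a national examination-survey extract used as the hot-deck donor
#' pool: adult records with smoking, diabetes, hypertension and
#' hyperlipidemia status plus systolic blood pressure, total cholesterol and
#' HDL cholesterol. Biomarkers drift mildly with age and sex; condition
#' prevalences rise with age on the logit scale.
#'
#' @param n number of donor records (at least 1).
#' @param seed integer seed.
#' @param biomarkers list of biomarker parameters; defaults give population
#'   means near 122 mm Hg systolic pressure, 189 mg/dL total cholesterol and
#'   52 mg/dL HDL-C.
#' @param prevalence named list of baseline prevalences at age 50
#'   (`smoking`, `diabetes`, `hypertension`, `hyperlipidemia`).
#' @param age_range donor age range (default 18-95, uniform).
#' @return data frame of donor records (one per row).
#' @export
gen_survey_pool <- function(n, seed = 1L,
                            biomarkers = list(
                              sbp_mean = 122, sbp_sd = 13, sbp_age_slope = 0.35,
                              chol_mean = 189, chol_sd = 36, chol_age_slope = 0.3,
                              hdl_mean = 52, hdl_sd = 13, hdl_female_shift = 8),
                            prevalence = list(
                              smoking = 0.155, diabetes = 0.10,
                              hypertension = 0.32, hyperlipidemia = 0.30),
                            age_range = c(18, 95)) {
  if (length(n) != 1L || !is.finite(n) || n < 1) {
    abort_arg("`n` must be a positive integer")
  }
  for (p in names(prevalence)) {
    if (prevalence[[p]] < 0 || prevalence[[p]] > 1) {
      abort_arg(sprintf("prevalence `%s` must be in [0, 1]", p))
    }
  }
  with_seed(seed, {
    age <- stats::runif(n, age_range[1], age_range[2])
    sex <- sample(c("male", "female"), n, replace = TRUE)
    male <- sex == "male"
    agec <- age - 50
    prev_at <- function(p0, slope) {
      if (p0 <= 0) return(rep(0, n))
      if (p0 >= 1) return(rep(1, n))
      stats::plogis(stats::qlogis(p0) + slope * agec)
    }
    sbp <- biomarkers$sbp_mean + biomarkers$sbp_age_slope * agec +
      3 * male + stats::rnorm(n, 0, biomarkers$sbp_sd)
    chol <- biomarkers$chol_mean + biomarkers$chol_age_slope * agec +
      stats::rnorm(n, 0, biomarkers$chol_sd)
    hdl <- biomarkers$hdl_mean - biomarkers$hdl_female_shift / 2 +
      biomarkers$hdl_female_shift * (!male) + stats::rnorm(n, 0, biomarkers$hdl_sd)
    data.frame(
      age = age, sex = sex,
      smoking = stats::runif(n) < prev_at(prevalence$smoking, 0),
      diabetes = stats::runif(n) < prev_at(prevalence$diabetes, 0.045),
      hypertension = stats::runif(n) < prev_at(prevalence$hypertension, 0.055),
      hyperlipidemia = stats::runif(n) < prev_at(prevalence$hyperlipidemia, 0.04),
      sbp = pmax(sbp, 70),
      total_chol = pmax(chol, 80),
      hdl = pmax(hdl, 15),
      stringsAsFactors = FALSE)
  })
}

# Claims-eligible adult count per tract: residents in the 20-24 band and
# older (claims tables are reported for adults; the 15-19 band straddles the
# age-18 eligibility boundary and is left out of the claims denominator).
claims_adults <- function(demographics) {
  adult_bands <- age_bands()[5:18]
  a <- demographics[demographics$age_band %in% adult_bands, , drop = FALSE]
  stats::aggregate(count ~ tract_id, data = a, FUN = sum)
}

#' Generate tract-level condition claim counts
#'
#' Emulates insurer claim counts per tract and condition: a binomial draw
#' over each tract's claims-eligible adults at the configured prevalence.
#'
#' @param tracts a `tract_set`.
#' @param demographics demographic cell table from [gen_demographics()].
#' @param condition_prevalences named fractions in \[0, 1\] per condition.
#' @param seed integer seed.
#' @return data frame with columns `tract_id`, `condition`, `count`.
#' @export
gen_claims <- function(tracts, demographics,
                       condition_prevalences = c(diabetes = 0.10,
                                                 hypertension = 0.32,
                                                 hyperlipidemia = 0.30),
                       seed = 1L) {
  stopifnot(inherits(tracts, "tract_set"))
  if (any(condition_prevalences < 0) || any(condition_prevalences > 1)) {
    abort_arg("condition prevalences must lie in [0, 1]")
  }
  adults <- claims_adults(demographics)
  adults <- adults[match(tracts$tracts$tract_id, adults$tract_id), ]
  conds <- names(condition_prevalences)
  with_seed(seed, {
    out <- lapply(conds, function(cn) {
      data.frame(tract_id = adults$tract_id,
                 condition = cn,
                 count = stats::rbinom(nrow(adults), adults$count,
                                       condition_prevalences[[cn]]),
                 stringsAsFactors = FALSE)
    })
  })
  do.call(rbind, out)
}

#' Default social and biological determinant specification
#'
#' Twenty social determinants plus three biological (condition-prevalence)
#' determinants typical of county open-data portals: percentages of
#' households or persons (0-100 scale), dollar amounts, and index values.
#' Each has a generating mean and SD, clamping range, and an orientation
#' (`favorable_high` if larger values are better).
#'
#' @return data frame with columns `name`, `mean`, `sd`, `min`, `max`,
#'   `orientation`, `group` (`social` or `biological`).
#' @export
default_determinant_spec <- function() {
  d <- function(name, mean, sd, min, max, orientation, group = "social") {
    data.frame(name = name, mean = mean, sd = sd, min = min, max = max,
               orientation = orientation, group = group,
               stringsAsFactors = FALSE)
  }
  rbind(
    d("pct_food_stamps",    15,    10,   0, 100, "favorable_low"),
    d("pct_no_jobs",         8,     4,   0, 100, "favorable_low"),
    d("median_income",   50000, 15000, 5e3, 3e5, "favorable_high"),
    d("pct_hs_grad",        88,     8,   0, 100, "favorable_high"),
    d("pct_college_grad",   35,    15,   0, 100, "favorable_high"),
    d("pct_below_poverty_hh", 12,   9,   0, 100, "favorable_low"),
    d("pct_below_poverty_ind", 14, 10,   0, 100, "favorable_low"),
    d("poverty_index",     100,    60,   0, 1e3, "favorable_low"),
    d("pct_no_insurance",    9,     5,   0, 100, "favorable_low"),
    d("pct_vacant_houses",   8,     6,   0, 100, "favorable_low"),
    d("pct_no_vehicle",     12,     8,   0, 100, "favorable_low"),
    d("pct_renting",        35,    15,   0, 100, "favorable_low"),
    d("pct_poor_condition",  6,     4,   0, 100, "favorable_low"),
    d("particulate_matter", 10,     2,   0, 100, "favorable_low"),
    d("walk_score",         45,    20,   0, 100, "favorable_high"),
    d("n_supermarkets",      1.5,   1,   0,  50, "favorable_high"),
    d("n_fast_food",         3,     2,   0, 100, "favorable_low"),
    d("homicide_count",      0.8,   1,   0, 100, "favorable_low"),
    d("median_age",         41,     6,  15,  90, "favorable_low"),
    d("pct_obese",          30,     8,   0, 100, "favorable_low"),
    d("pct_diabetes",       10,     4,   0, 100, "favorable_low", "biological"),
    d("pct_hypertension",   32,     8,   0, 100, "favorable_low", "biological"),
    d("pct_hyperlipidemia", 30,     8,   0, 100, "favorable_low", "biological"))
}

# One-step rook-neighbor smoothing: x' = (1 - rho) * x + rho * neighbor mean.
neighbor_smooth <- function(x, adjacency, ids, rho) {
  if (rho == 0) return(x)
  nb_mean <- vapply(seq_along(ids), function(i) {
    nb <- match(adjacency[[ids[i]]], ids)
    if (length(nb) == 0L) x[i] else mean(x[nb])
  }, numeric(1))
  (1 - rho) * x + rho * nb_mean
}

#' Generate spatially autocorrelated determinant tables
#'
#' Each determinant is an independent Gaussian field smoothed once over rook
#' neighbors with mixing weight `spatial_rho`, rescaled to the target mean
#' and SD, and clamped to its plausible range. Different determinants are
#' generated from independent fields, so they are uncorrelated with each
#' other by construction.
#'
#' @param tracts a `tract_set`.
#' @param spec determinant specification, see [default_determinant_spec()].
#' @param spatial_rho neighbor-mixing weight in \[0, 1).
#' @param seed integer seed.
#' @return data frame with `tract_id` plus one column per determinant;
#'   attribute `orientation` is a named character vector.
#' @export
gen_determinants <- function(tracts, spec = default_determinant_spec(),
                             spatial_rho = 0.5, seed = 1L) {
  stopifnot(inherits(tracts, "tract_set"))
  if (spatial_rho < 0 || spatial_rho >= 1) {
    abort_arg("`spatial_rho` must lie in [0, 1)")
  }
  ids <- tracts$tracts$tract_id
  n <- length(ids)
  out <- data.frame(tract_id = ids, stringsAsFactors = FALSE)
  with_seed(seed, {
    for (k in seq_len(nrow(spec))) {
      e <- stats::rnorm(n)
      s <- neighbor_smooth(e, tracts$adjacency, ids, spatial_rho)
      z <- (s - mean(s)) / stats::sd(s)
      x <- spec$mean[k] + spec$sd[k] * z
      out[[spec$name[k]]] <- pmin(pmax(x, spec$min[k]), spec$max[k])
    }
  })
  attr(out, "orientation") <- stats::setNames(spec$orientation, spec$name)
  out
}

#' Ground truth for a generated dataset
#'
#' Records the planted determinant effects (per 100 000 difference units per
#' determinant unit), the SD of the tract-level noise added to the planted
#' difference (per 100 000), the spatial autocorrelation weight used for the
#' determinants, and the master seed. Serialized next to every generated
#' dataset so recovery tests read, never hard-code, the truth.
#'
#' @param determinant_effects named numeric vector of planted slopes.
#' @param intercept level term of the planted difference, per 100 000. The
#'   default centers the difference implied by the default effects over the
#'   default determinant means near -40 per 100 000, so roughly half the
#'   tracts end up in excess (observed above expected).
#' @param noise_sd nonnegative noise SD on the per-100 000 difference scale.
#' @param spatial_rho autocorrelation weight in \[0, 1).
#' @param seed integer master seed.
#' @return object of class `ground_truth`.
#' @export
ground_truth <- function(determinant_effects = c(pct_food_stamps = -20,
                                                 pct_no_jobs = -20,
                                                 pct_hs_grad = 25,
                                                 median_income = 0.004),
                         intercept = -1980,
                         noise_sd = 300, spatial_rho = 0.5, seed = 1L) {
  if (noise_sd < 0) abort_arg("`noise_sd` must be nonnegative")
  if (spatial_rho < 0 || spatial_rho >= 1) {
    abort_arg("`spatial_rho` must lie in [0, 1)")
  }
  if (length(determinant_effects) > 0 && is.null(names(determinant_effects))) {
    abort_arg("`determinant_effects` must be named")
  }
  if (length(intercept) != 1L || !is.finite(intercept)) {
    abort_arg("`intercept` must be a single finite number")
  }
  structure(list(determinant_effects = determinant_effects,
                 intercept = intercept,
                 noise_sd = noise_sd, spatial_rho = spatial_rho,
                 seed = as.integer(seed)),
            class = "ground_truth")
}

#' Generate observed tract death counts with a planted excess-risk structure
#'
#' Inverts the analysis: the planted per-tract difference (expected minus
#' observed, per 100 000) is the linear predictor of the ground-truth
#' determinant effects plus zero-mean Gaussian noise. The implied observed
#' age-standardized rate is `expected_per_100k - difference`, floored at 0,
#' and death counts are spread over age bands at a common band rate so that
#' direct age standardization recovers the planted rate.
#'
#' @param expected tract expected-risk table from [expected_tract_risk()]
#'   (columns `tract_id`, `expected_per_100k`).
#' @param demographics demographic cell table (band populations).
#' @param determinants determinant table covering every expected tract.
#' @param truth a [ground_truth()] object.
#' @param seed integer seed for the noise draw.
#' @param realization `"rounded"` (deterministic integer rounding of band
#'   expected deaths, the default), `"fractional"` (no rounding, exact planted
#'   structure; the natural choice for noiseless configurations), or
#'   `"binomial"` (stochastic realization at the band rate).
#' @return data frame `tract_id`, `age_band`, `deaths`, with attribute
#'   `planted_difference` (data frame of the planted per-tract differences).
#' @export
gen_observed_deaths <- function(expected, demographics, determinants, truth,
                                seed = 1L,
                                realization = c("rounded", "fractional",
                                                "binomial")) {
  realization <- match.arg(realization)
  stopifnot(inherits(truth, "ground_truth"))
  ids <- expected$tract_id
  missing_tr <- setdiff(ids, determinants$tract_id)
  if (length(missing_tr) > 0) {
    abort_data(sprintf("determinant table is missing tract(s): %s",
                       paste(missing_tr, collapse = ", ")))
  }
  eff <- truth$determinant_effects
  missing_det <- setdiff(names(eff), names(determinants))
  if (length(missing_det) > 0) {
    abort_data(sprintf("determinant column(s) not found: %s",
                       paste(missing_det, collapse = ", ")))
  }
  det <- determinants[match(ids, determinants$tract_id), , drop = FALSE]
  lp <- rep(truth$intercept, length(ids))
  for (nm in names(eff)) lp <- lp + eff[[nm]] * det[[nm]]
  eps <- if (truth$noise_sd > 0) {
    with_seed(seed, stats::rnorm(length(ids), 0, truth$noise_sd))
  } else {
    rep(0, length(ids))
  }
  difference <- lp + eps
  observed_rate <- pmax(expected$expected_per_100k - difference, 0)

  pop_band <- stats::aggregate(count ~ tract_id + age_band,
                               data = demographics, FUN = sum)
  pop_band <- pop_band[pop_band$tract_id %in% ids, ]
  rate <- observed_rate[match(pop_band$tract_id, ids)] / 1e5
  deaths <- rate * pop_band$count
  if (realization == "rounded") {
    deaths <- round(deaths)
  } else if (realization == "binomial") {
    deaths <- with_seed(derive_seed(seed, 7L), {
      stats::rbinom(length(deaths), pop_band$count, pmin(rate, 1))
    })
  }
  out <- data.frame(tract_id = pop_band$tract_id,
                    age_band = pop_band$age_band,
                    deaths = deaths, stringsAsFactors = FALSE)
  out <- out[order(out$tract_id, match(out$age_band, age_bands())), ]
  rownames(out) <- NULL
  attr(out, "planted_difference") <-
    data.frame(tract_id = ids, difference_per_100k = difference,
               stringsAsFactors = FALSE)
  out
}

# ---- serialization ----------------------------------------------------------

#' Write a tract set as GeoJSON
#'
#' One Feature per tract with properties `tract_id` and `neighbors`
#' (pipe-separated), so adjacency round-trips losslessly.
#'
#' @param tracts a `tract_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tracts_geojson <- function(tracts, path) {
  stopifnot(inherits(tracts, "tract_set"))
  feats <- lapply(seq_len(nrow(tracts$tracts)), function(i) {
    id <- tracts$tracts$tract_id[i]
    ring <- tracts$geometry[[id]]
    list(type = "Feature",
         properties = list(tract_id = id,
                           row = tracts$tracts$row[i],
                           col = tracts$tracts$col[i],
                           neighbors = paste(tracts$adjacency[[id]],
                                             collapse = "|")),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(j) unname(ring[j, ])))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a tract set from GeoJSON written by [write_tracts_geojson()]
#'
#' @param path input path.
#' @return a `tract_set`.
#' @export
read_tracts_geojson <- function(path) {
  if (!file.exists(path)) abort_data(sprintf("file not found: %s", path))
  gj <- jsonlite::read_json(path)
  feats <- gj$features
  ids <- vapply(feats, function(f) f$properties$tract_id, character(1))
  rows <- vapply(feats, function(f) as.integer(f$properties$row), integer(1))
  cols <- vapply(feats, function(f) as.integer(f$properties$col), integer(1))
  adjacency <- lapply(feats, function(f) {
    nb <- f$properties$neighbors
    if (is.null(nb) || identical(nb, "")) character(0)
    else strsplit(nb, "|", fixed = TRUE)[[1]]
  })
  names(adjacency) <- ids
  geometry <- lapply(feats, function(f) {
    ring <- f$geometry$coordinates[[1]]
    m <- do.call(rbind, lapply(ring, function(p) as.numeric(unlist(p))))
    colnames(m) <- c("x", "y")
    m
  })
  names(geometry) <- ids
  structure(list(tracts = data.frame(tract_id = ids, row = rows, col = cols,
                                     stringsAsFactors = FALSE),
                 adjacency = adjacency, geometry = geometry),
            class = "tract_set")
}

#' Write ground truth as JSON
#' @param truth a [ground_truth()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  x <- unclass(truth)
  x$determinant_effects <- as.list(x$determinant_effects)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read ground truth JSON written by [write_ground_truth()]
#' @param path input path.
#' @return a `ground_truth` object.
#' @export
read_ground_truth <- function(path) {
  if (!file.exists(path)) abort_data(sprintf("file not found: %s", path))
  x <- jsonlite::read_json(path)
  ground_truth(determinant_effects = unlist(x$determinant_effects) %||% numeric(0),
               intercept = x$intercept %||% 0,
               noise_sd = x$noise_sd, spatial_rho = x$spatial_rho,
               seed = x$seed)
}
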