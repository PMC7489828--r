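# Semisynthetic population construction: expand demographic marginals into
# persons, assign claimed conditions per tract, and hot-deck impute biomarkers
# and remaining condition flags from a survey donor pool.

#' Expand demographic cells into an individual-level population
#'
#' Creates exactly `sum(count)` persons. Each person's age is drawn uniformly
#' within its five-year band (the open 85+ band spans 85-100).
#'
#' @param cells demographic cell table (`tract_id`, `age_band`, `sex`,
#'   `count`), e.g. from [gen_demographics()].
#' @param seed integer seed for the within-band age draws.
#' @return data frame of persons with columns `person_id`, `tract_id`, `age`,
#'   `age_band`, `sex`; condition flags (`smoking`, `diabetes`,
#'   `hypertension`, `hyperlipidemia`) initialised to `NA`, biomarkers
#'   (`sbp`, `total_chol`, `hdl`) to `NA`, and `claims_covered` to `FALSE`.
#' @export
expand_cells <- function(cells, seed = 1L) {
  req <- c("tract_id", "age_band", "sex", "count")
  if (!all(req %in% names(cells))) {
    abort_arg("`cells` must have columns tract_id, age_band, sex, count")
  }
  bad <- setdiff(unique(cells$age_band), age_bands())
  if (length(bad) > 0) {
    abort_data(sprintf("unknown age band label(s): %s",
                       paste(bad, collapse = ", ")))
  }
  if (any(cells$count < 0)) abort_data("cell counts must be nonnegative")
  idx <- rep(seq_len(nrow(cells)), times = cells$count)
  n <- length(idx)
  band <- cells$age_band[idx]
  lower <- band_lower(band)
  width <- band_width(band)
  age <- with_seed(seed, lower + stats::runif(n) * width)
  data.frame(
    person_id = sprintf("P%07d", seq_len(n)),
    tract_id = cells$tract_id[idx],
    age = age,
    age_band = band,
    sex = cells$sex[idx],
    smoking = rep(NA, n), diabetes = rep(NA, n), hypertension = rep(NA, n),
    hyperlipidemia = rep(NA, n), sbp = rep(NA_real_, n),
    total_chol = rep(NA_real_, n), hdl = rep(NA_real_, n),
    claims_covered = rep(FALSE, n),
    stringsAsFactors = FALSE)
}

# Adults are persons strictly older than 18; younger persons carry zero risk
# and are excluded from claims eligibility and donor matching.
is_adult <- function(persons) persons$age > 18

#' Assign claimed conditions to a claims-covered subset of each tract
#'
#' Within each tract, a claims-covered subset of adults of size
#' `round(coverage_fraction * n_adults)` is sampled; for each condition,
#' `min(count, subset size)` covered adults are flagged (a count exceeding
#' the subset is clipped with a warning). Covered adults not flagged get an
#' explicit `FALSE` for that condition: the claims record is authoritative
#' for the covered subpopulation. Uncovered adults keep `NA` flags until
#' donor imputation; persons aged 18 or younger get all-`FALSE` flags.
#'
#' @param persons person table from [expand_cells()].
#' @param claims claim-count table (`tract_id`, `condition`, `count`).
#' @param coverage_fraction fraction of adults covered by claims data,
#'   in \[0, 1\] (default 0.8).
#' @param seed integer seed.
#' @return the person table with condition flags and `claims_covered` set.
#' @export
assign_conditions <- function(persons, claims, coverage_fraction = 0.8,
                              seed = 1L) {
  if (coverage_fraction < 0 || coverage_fraction > 1) {
    abort_arg("`coverage_fraction` must lie in [0, 1]")
  }
  unknown <- setdiff(unique(claims$tract_id), unique(persons$tract_id))
  if (length(unknown) > 0) {
    abort_data(sprintf("claims refer to unknown tract(s): %s",
                       paste(unknown, collapse = ", ")))
  }
  conds <- intersect(unique(claims$condition),
                     c("diabetes", "hypertension", "hyperlipidemia"))
  adult <- is_adult(persons)
  persons[!adult, c("smoking", "diabetes", "hypertension",
                    "hyperlipidemia")] <- FALSE
  adult_rows <- which(adult)
  adults_by_tract <- split(adult_rows, persons$tract_id[adult_rows])
  covered <- persons$claims_covered
  flags <- lapply(conds, function(cn) persons[[cn]])
  names(flags) <- conds
  claims_by_tract <- split(claims, claims$tract_id)
  with_seed(seed, {
    for (tid in names(claims_by_tract)) {
      aidx <- adults_by_tract[[tid]] %||% integer(0)
      n_cov <- round(coverage_fraction * length(aidx))
      cov <- aidx[sample.int(length(aidx), n_cov)]
      covered[cov] <- TRUE
      for (cn in conds) flags[[cn]][cov] <- FALSE
      tcl <- claims_by_tract[[tid]]
      for (k in seq_len(nrow(tcl))) {
        cn <- tcl$condition[k]
        if (!cn %in% conds) next
        want <- tcl$count[k]
        take <- min(want, n_cov)
        if (want > n_cov) {
          warning(sprintf(
            "tract %s: %s claim count %d exceeds %d covered adults; clipped",
            tid, cn, want, n_cov), call. = FALSE)
        }
        if (take > 0) {
          flags[[cn]][cov[sample.int(length(cov), take)]] <- TRUE
        }
      }
    }
  })
  persons$claims_covered <- covered
  for (cn in conds) persons[[cn]] <- flags[[cn]]
  persons
}

# Donor stratum lookup: exact (sex, band), then (sex, band +/- 1), then sex.
match_stratum <- function(sex, band, pool_sex, pool_band) {
  bands <- age_bands()
  bi <- match(band, bands)
  exact <- which(pool_sex == sex & pool_band == band)
  if (length(exact) > 0) return(list(idx = exact, fallback = "exact"))
  near_bands <- bands[c(bi - 1L, bi + 1L)]
  near_bands <- near_bands[!is.na(near_bands)]
  near <- which(pool_sex == sex & pool_band %in% near_bands)
  if (length(near) > 0) return(list(idx = near, fallback = "adjacent_band"))
  any_sex <- which(pool_sex == sex)
  if (length(any_sex) > 0) return(list(idx = any_sex, fallback = "sex_only"))
  list(idx = seq_along(pool_sex), fallback = "pool")
}

#' Hot-deck impute biomarkers and remaining condition flags from donors
#'
#' Every adult is matched to a donor agreeing on sex and five-year age band;
#' if the exact stratum is empty the match widens to the adjacent bands, then
#' to sex only. The donor's continuous biomarkers (and smoking flag) are
#' copied to the person. For claims-covered persons the claimed condition
#' flags are preserved; uncovered adults take all condition flags from the
#' donor. Persons aged 18 or younger are not matched (their risk is zero by
#' construction).
#'
#' @param persons person table (after [assign_conditions()], or directly
#'   after [expand_cells()], in which case every adult takes donor flags).
#' @param pool donor table from [gen_survey_pool()] (nonempty).
#' @param seed integer seed; donors are sampled uniformly with replacement
#'   within the stratum.
#' @return the person table with `sbp`, `total_chol`, `hdl`, `smoking` filled
#'   for adults, plus condition flags for uncovered adults. Attribute
#'   `fallback_counts` tabulates the match levels used.
#' @export
impute_from_donors <- function(persons, pool, seed = 1L) {
  if (is.null(pool) || nrow(pool) == 0) {
    abort_arg("donor pool must be nonempty")
  }
  pool_band <- band_of_age(pool$age)
  adult <- which(is_adult(persons))
  donor_of <- integer(length(adult))
  fallback <- character(length(adult))
  strata <- split(seq_along(adult),
                  paste(persons$sex[adult], persons$age_band[adult]))
  with_seed(seed, {
    for (key in names(strata)) {
      members <- strata[[key]]
      p1 <- adult[members[1]]
      m <- match_stratum(persons$sex[p1], persons$age_band[p1],
                         pool$sex, pool_band)
      donor_of[members] <- m$idx[sample.int(length(m$idx), length(members),
                                            replace = TRUE)]
      fallback[members] <- m$fallback
    }
  })
  rows <- adult
  persons$sbp[rows] <- pool$sbp[donor_of]
  persons$total_chol[rows] <- pool$total_chol[donor_of]
  persons$hdl[rows] <- pool$hdl[donor_of]
  persons$smoking[rows] <- pool$smoking[donor_of]
  for (cn in c("diabetes", "hypertension", "hyperlipidemia")) {
    fill <- is.na(persons[[cn]][rows])
    persons[[cn]][rows[fill]] <- pool[[cn]][donor_of[fill]]
  }
  attr(persons, "fallback_counts") <- table(fallback)
  persons
}

#' Summarize a population the way county health reports tabulate it
#'
#' Whole-population means plus per-tract values with across-tract range,
#' mean and SD for age, percent male, percent smokers, percent with
#' diabetes, total cholesterol, systolic blood pressure and HDL-C.
#' Percent/biomarker summaries are computed over persons with observed
#' values (adults, once imputation has run).
#'
#' @param persons person table.
#' @return object of class `population_summary`: list with `overall` (named
#'   list), `per_tract` (data frame) and `across_tracts` (data frame of
#'   min/max/mean/sd per characteristic).
#' @export
summarize_population <- function(persons) {
  if (is.null(persons) || nrow(persons) == 0) {
    abort_arg("population must be nonempty")
  }
  pct <- function(x) 100 * mean(x, na.rm = TRUE)
  mn <- function(x) mean(x, na.rm = TRUE)
  characteristics <- function(df) {
    list(n = nrow(df),
         mean_age = mn(df$age), sd_age = stats::sd(df$age),
         pct_male = pct(df$sex == "male"),
         pct_smoker = pct(df$smoking),
         pct_diabetes = pct(df$diabetes),
         mean_total_chol = mn(df$total_chol),
         mean_sbp = mn(df$sbp),
         mean_hdl = mn(df$hdl))
  }
  overall <- characteristics(persons)
  per_tract <- do.call(rbind, lapply(split(persons, persons$tract_id),
                                     function(df) {
    as.data.frame(c(list(tract_id = df$tract_id[1]), characteristics(df)),
                  stringsAsFactors = FALSE)
  }))
  rownames(per_tract) <- NULL
  vars <- setdiff(names(per_tract), c("tract_id", "n"))
  safe <- function(f, x) {
    x <- x[!is.na(x)]
    if (length(x) == 0) NA_real_ else f(x)
  }
  across <- data.frame(
    characteristic = vars,
    min = vapply(vars, function(v) safe(min, per_tract[[v]]), 0),
    max = vapply(vars, function(v) safe(max, per_tract[[v]]), 0),
    mean = vapply(vars, function(v) safe(mean, per_tract[[v]]), 0),
    sd = vapply(vars, function(v) safe(stats::sd, per_tract[[v]]), 0),
    stringsAsFactors = FALSE)
  rownames(across) <- NULL
  structure(list(overall = overall, per_tract = per_tract,
                 across_tracts = across),
            class = "population_summary")
}

#' @export
print.population_summary <- function(x, ...) {
  o <- x$overall
  cat(sprintf("Population: %d persons in %d tracts\n",
              o$n, nrow(x$per_tract)))
  cat(sprintf("  mean (SD) age: %.1f (%.1f) y; %% male: %.1f\n",
              o$mean_age, o$sd_age, o$pct_male))
  cat(sprintf("  %% smoker: %.1f; %% diabetes: %.1f\n",
              o$pct_smoker, o$pct_diabetes))
  cat(sprintf("  mean total chol: %.1f mg/dL; mean SBP: %.1f mm Hg; mean HDL-C: %.1f mg/dL\n",
              o$mean_total_chol, o$mean_sbp, o$mean_hdl))
  invisible(x)
}
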