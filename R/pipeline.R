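# End-to-end orchestration: simulate or load inputs, build the population,
# compute expected and observed risk, the excess-risk surface, its spatial
# clustering, determinant regressions and counterfactual scenarios.
# All file interchange is headered CSV with a provenance comment line,
# GeoJSON for geometry, JSON for configs and results.

# Cheap deterministic config fingerprint for provenance lines; filesystem
# locations are excluded so the hash identifies the analysis, not the paths.
config_hash <- function(config) {
  config <- config[setdiff(names(config), c("out_dir", "input_dir"))]
  s <- paste(deparse(config), collapse = "")
  v <- utf8ToInt(s)
  sprintf("%08x", sum(v * (seq_along(v) %% 97 + 1)) %% 4294967291)
}

#' Simulate a complete input bundle with known ground truth
#'
#' Runs every generator in dependency order: tract lattice, demographic
#' marginals, survey donor pool, claim counts, determinant tables; then
#' builds the semisynthetic population, computes tract expected risk under
#' the risk model, and generates observed death counts around the planted
#' difference structure.
#'
#' @param n_rows,n_cols lattice dimensions.
#' @param seed master integer seed (sub-seeds are derived per generator).
#' @param mean_pop mean tract population (default 3414).
#' @param survey_n donor pool size (default 5000).
#' @param coverage_fraction claims coverage fraction of adults (default 0.8).
#' @param truth a [ground_truth()] (defaults to the package default truth).
#' @param model a [risk_model()] (defaults to [default_risk_model()]).
#' @param determinant_spec see [default_determinant_spec()].
#' @param realization death-count realization, see [gen_observed_deaths()].
#' @return list with elements `tracts`, `demographics`, `survey`, `claims`,
#'   `determinants`, `truth`, `model`, `persons`, `expected`, `deaths`,
#'   `seed`.
#' @export
simulate_inputs <- function(n_rows, n_cols, seed = 1L, mean_pop = 3414,
                            survey_n = 5000, coverage_fraction = 0.8,
                            truth = ground_truth(seed = seed),
                            model = default_risk_model(),
                            determinant_spec = default_determinant_spec(),
                            realization = "rounded") {
  tracts <- gen_tract_lattice(n_rows, n_cols, seed = seed)
  demographics <- gen_demographics(tracts, mean_pop = mean_pop,
                                   seed = derive_seed(seed, 1L))
  survey <- gen_survey_pool(survey_n, seed = derive_seed(seed, 2L))
  claims <- gen_claims(tracts, demographics, seed = derive_seed(seed, 3L))
  determinants <- gen_determinants(tracts, spec = determinant_spec,
                                   spatial_rho = truth$spatial_rho,
                                   seed = derive_seed(seed, 4L))
  persons <- expand_cells(demographics, seed = derive_seed(seed, 5L))
  persons <- assign_conditions(persons, claims,
                               coverage_fraction = coverage_fraction,
                               seed = derive_seed(seed, 6L))
  persons <- impute_from_donors(persons, survey, seed = derive_seed(seed, 7L))
  expected <- expected_tract_risk(persons, model)
  deaths <- gen_observed_deaths(expected, demographics, determinants, truth,
                                seed = derive_seed(seed, 8L),
                                realization = realization)
  list(tracts = tracts, demographics = demographics, survey = survey,
       claims = claims, determinants = determinants, truth = truth,
       model = model, persons = persons, expected = expected,
       deaths = deaths, seed = as.integer(seed))
}

#' Write a simulated input bundle to a directory
#'
#' Writes `tracts.geojson`, `demographics.csv`, `survey.csv`, `claims.csv`,
#' `determinants.csv`, `orientation.json`, `deaths.csv`, `truth.json` and
#' `risk_model.json`. The ground truth is always serialized next to the data
#' it generated.
#'
#' @param sim bundle from [simulate_inputs()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_tracts_geojson(sim$tracts, p("tracts.geojson"))
  write_tract_csv(sim$demographics, p("demographics.csv"), seed = sim$seed)
  write_tract_csv(sim$survey, p("survey.csv"), seed = sim$seed)
  write_tract_csv(sim$claims, p("claims.csv"), seed = sim$seed)
  write_tract_csv(sim$determinants, p("determinants.csv"), seed = sim$seed)
  jsonlite::write_json(as.list(attr(sim$determinants, "orientation")),
                       p("orientation.json"), auto_unbox = TRUE)
  write_tract_csv(sim$deaths, p("deaths.csv"), seed = sim$seed)
  write_ground_truth(sim$truth, p("truth.json"))
  write_risk_model(sim$model, p("risk_model.json"))
  invisible(dir)
}

#' Read an input bundle written by [write_sim_dataset()]
#'
#' @param dir directory path.
#' @return list with `tracts`, `demographics`, `survey`, `claims`,
#'   `determinants` (with `orientation` attribute), `deaths`, `truth`,
#'   `model`.
#' @export
read_sim_dataset <- function(dir) {
  p <- function(f) file.path(dir, f)
  determinants <- read_tract_csv(p("determinants.csv"))
  ori <- jsonlite::read_json(p("orientation.json"), simplifyVector = TRUE)
  attr(determinants, "orientation") <- unlist(ori)
  list(tracts = read_tracts_geojson(p("tracts.geojson")),
       demographics = read_tract_csv(p("demographics.csv")),
       survey = read_tract_csv(p("survey.csv")),
       claims = read_tract_csv(p("claims.csv")),
       determinants = determinants,
       deaths = read_tract_csv(p("deaths.csv")),
       truth = read_ground_truth(p("truth.json")),
       model = read_risk_model(p("risk_model.json")))
}

# Run one pipeline stage, prefixing any error with the stage name so a
# failure is attributable to its input.
run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(errorCondition(sprintf("stage %s: %s", name, conditionMessage(e)),
                        class = unique(c(class(e)[!class(e) %in%
                                                    c("error", "condition")],
                                         "tractrisk_stage_error", "error"))))
  })
}

#' Run the full excess-risk pipeline
#'
#' Executes, in order: input simulation or loading; population build
#' (expand, claims assignment, donor imputation); expected tract risk;
#' observed age-standardized rates and the expected-minus-observed
#' difference; the calibration regression; global Moran's I with a
#' permutation test; the Bonferroni-corrected univariate screen, backward
#' stepwise multivariate model and rank composite; and the 10%/20%
#' determinant-improvement scenarios under the stepwise model.
#'
#' @param config list with any of: `seed` (default 1), `out_dir` (results are
#'   written there when given), `input_dir` (read a previously written bundle
#'   instead of simulating), `sim` (list of [simulate_inputs()] arguments:
#'   `n_rows`, `n_cols`, `mean_pop`, ...), `coverage_fraction` (0.8),
#'   `min_population` (50), `n_permutations` (999), `scheme` (`"rook"`),
#'   `screen_determinants` (optional character vector restricting the
#'   univariate screen), `scenario_magnitudes` (c(0.10, 0.20)),
#'   `write_population` (FALSE).
#' @return list with `summary`, `calibration`, `moran`, `screen`, `stepwise`,
#'   `composite`, `scenarios`, `population_summary`, `expected`, `persons`
#'   (invisible components of the run), plus `config`.
#' @export
run_pipeline <- function(config = list()) {
  seed <- config$seed %||% 1L
  sim_args <- config$sim %||% list(n_rows = 6, n_cols = 6)

  if (!is.null(config$input_dir)) {
    p_in <- function(f) file.path(config$input_dir, f)
    inputs <- run_stage("inputs", {
      determinants <- read_tract_csv(p_in("determinants.csv"))
      ori <- jsonlite::read_json(p_in("orientation.json"),
                                 simplifyVector = TRUE)
      attr(determinants, "orientation") <- unlist(ori)
      list(tracts = read_tracts_geojson(p_in("tracts.geojson")),
           demographics = read_tract_csv(p_in("demographics.csv")),
           determinants = determinants,
           deaths = read_tract_csv(p_in("deaths.csv")),
           truth = read_ground_truth(p_in("truth.json")),
           model = read_risk_model(p_in("risk_model.json")))
    })
    persons <- run_stage("population", {
      claims <- read_tract_csv(p_in("claims.csv"))
      survey <- read_tract_csv(p_in("survey.csv"))
      pp <- expand_cells(inputs$demographics, seed = derive_seed(seed, 5L))
      pp <- assign_conditions(pp, claims,
                              coverage_fraction = config$coverage_fraction %||% 0.8,
                              seed = derive_seed(seed, 6L))
      impute_from_donors(pp, survey, seed = derive_seed(seed, 7L))
    })
    expected <- run_stage("risk", expected_tract_risk(persons, inputs$model))
    sim <- c(inputs, list(persons = persons, expected = expected, seed = seed))
  } else {
    sim <- run_stage("inputs", do.call(simulate_inputs, c(
      sim_args,
      list(seed = seed,
           coverage_fraction = config$coverage_fraction %||% 0.8))))
    if (!is.null(config$out_dir)) {
      run_stage("inputs", write_sim_dataset(sim, file.path(config$out_dir,
                                                           "inputs")))
    }
    expected <- sim$expected
  }

  excess <- run_stage("excess", {
    observed <- observed_tract_rates(sim$deaths, sim$demographics)
    summary <- risk_difference(expected, observed,
                               min_population = config$min_population %||% 50)
    list(observed = observed, summary = summary,
         calibration = calibration_regression(summary))
  })
  summary <- excess$summary

  moran <- run_stage("spatial", {
    w <- build_weights(sim$tracts, scheme = config$scheme %||% "rook")
    vals <- summary$difference_per_100k[match(w$ids, summary$tract_id)]
    keep <- !is.na(vals)
    if (!all(keep)) {
      w <- build_weights(
        lapply(sim$tracts$adjacency[w$ids[keep]],
               function(nb) intersect(nb, w$ids[keep])))
    }
    morans_permutation(vals[keep], w,
                       n_permutations = config$n_permutations %||% 999,
                       seed = derive_seed(seed, 9L))
  })

  regress <- run_stage("determinants", {
    det <- sim$determinants
    screen_cols <- config$screen_determinants %||%
      setdiff(names(det), "tract_id")
    screen <- univariate_screen(
      summary, det[, c("tract_id", screen_cols), drop = FALSE])
    candidates <- screen$determinant[screen$significant]
    if (length(candidates) == 0) {
      # nothing survives Bonferroni (small runs): fall back to the
      # strongest univariate associations
      candidates <- screen$determinant[order(screen$p_value)][1:min(5, nrow(screen))]
    }
    # keep the design estimable: at most n - 3 candidate terms
    max_terms <- max(1L, nrow(summary) - 3L)
    if (length(candidates) > max_terms) {
      candidates <- candidates[seq_len(max_terms)]
    }
    stepwise <- backward_stepwise(summary, det, candidates)
    ori <- attr(det, "orientation")
    composite <- if (!is.null(ori)) {
      rank_composite(det, intersect(names(ori), screen_cols),
                     orientation = ori, summary = summary)
    } else NULL
    list(screen = screen, stepwise = stepwise, composite = composite)
  })

  scenarios <- run_stage("intervention", {
    mags <- config$scenario_magnitudes %||% c(0.10, 0.20)
    fit <- regress$stepwise$fit
    res <- lapply(mags, function(mg) {
      sc <- improvement_scenario(mg)
      sc$directions <- sc$directions[names(sc$directions) %in%
                                       names(sim$determinants)]
      modified <- apply_scenario(sim$determinants, sc)
      pred <- predict_difference(fit, summary, sim$determinants, modified)
      summarize_scenario(pred, summary)
    })
    names(res) <- sprintf("improve_%d", round(100 * mags))
    res
  })

  result <- list(summary = summary,
                 calibration = excess$calibration,
                 moran = moran,
                 screen = regress$screen,
                 stepwise = regress$stepwise,
                 composite = regress$composite,
                 scenarios = scenarios,
                 expected = expected,
                 persons = sim$persons,
                 truth = sim$truth,
                 config = config)

  if (!is.null(config$out_dir)) {
    run_stage("outputs", {
      dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
      p <- function(f) file.path(config$out_dir, f)
      write_tract_csv(as.data.frame(summary), p("summary.csv"), seed = seed)
      write_tract_csv(as.data.frame(regress$screen), p("screen.csv"),
                      seed = seed)
      if (isTRUE(config$write_population)) {
        write_tract_csv(sim$persons, p("population.csv"), seed = seed)
      }
      jsonlite::write_json(list(
        provenance = list(package = "tractrisk",
                          version = as.character(utils::packageVersion("tractrisk")),
                          seed = seed, config_hash = config_hash(config)),
        moran = unclass(moran)[c("I", "expected_I", "pseudo_p", "z",
                                 "n_permutations", "n", "alternative")],
        calibration = unclass(excess$calibration),
        stepwise = list(retained = regress$stepwise$retained,
                        trace = regress$stepwise$trace),
        scenarios = lapply(scenarios, function(s) {
          unclass(s)[c("n_negative_tracts", "negative_tract_population",
                       "total_population", "share_of_total_population")]
        }),
        excess_stats = attr(summary, "stats")),
        p("results.json"), auto_unbox = TRUE, digits = NA)
    })
  }
  result
}
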