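test_that("lattice adjacency is symmetric with correct neighbor counts", {
  tr <- gen_tract_lattice(3, 3, seed = 1)
  expect_equal(nrow(tr$tracts), 9)
  deg <- lengths(tr$adjacency)
  corners <- tr$tracts$tract_id[tr$tracts$row %in% c(1, 3) &
                                  tr$tracts$col %in% c(1, 3)]
  expect_true(all(deg[corners] == 2))
  expect_true(all(deg >= 2 & deg <= 4))
  for (id in tr$tracts$tract_id) {
    for (nb in tr$adjacency[[id]]) {
      expect_true(id %in% tr$adjacency[[nb]])
    }
    expect_false(id %in% tr$adjacency[[id]])
  }
})

test_that("a 1x2 lattice makes each tract the other's sole neighbor", {
  tr <- gen_tract_lattice(1, 2, seed = 1)
  ids <- tr$tracts$tract_id
  expect_equal(tr$adjacency[[ids[1]]], ids[2])
  expect_equal(tr$adjacency[[ids[2]]], ids[1])
})

test_that("lattice generation is deterministic and validates dimensions", {
  expect_identical(gen_tract_lattice(2, 2, seed = 7),
                   gen_tract_lattice(2, 2, seed = 7))
  expect_error(gen_tract_lattice(0, 3), class = "tractrisk_argument_error")
  expect_error(gen_tract_lattice(1, 1), class = "tractrisk_argument_error")
})

test_that("demographics honor degenerate weights and sex fractions", {
  tr <- gen_tract_lattice(2, 2, seed = 1)
  w <- setNames(rep(0, 18), age_bands())
  w["20-24"] <- 1
  d <- gen_demographics(tr, mean_pop = 100, age_band_weights = w,
                        pct_male = 1, seed = 3)
  on_cell <- d$age_band == "20-24" & d$sex == "male"
  expect_true(all(d$count[!on_cell] == 0))
  expect_true(sum(d$count[on_cell]) > 0)
})

test_that("tract totals follow the Poisson count model", {
  tr <- gen_tract_lattice(2, 2, seed = 1)
  d <- gen_demographics(tr, mean_pop = 250, seed = 3)
  total <- sum(d$count)
  # total of 4 tracts ~ Poisson(1000); central 99.9% interval
  expect_gte(total, qpois(0.0005, 1000))
  expect_lte(total, qpois(0.9995, 1000))
  expect_identical(d, gen_demographics(tr, mean_pop = 250, seed = 3))
  expect_error(gen_demographics(tr, age_band_weights = rep(0.1, 18)),
               class = "tractrisk_argument_error")
})

test_that("survey pool means match the configured generator distribution", {
  pool <- gen_survey_pool(1000, seed = 5)
  # ages uniform on (18, 95): mean cholesterol = 189 + 0.3 * (56.5 - 50)
  mu <- 189 + 0.3 * (56.5 - 50)
  sd_theory <- sqrt(36^2 + (0.3 * (95 - 18) / sqrt(12))^2)
  expect_lt(abs(mean(pool$total_chol) - mu), 3 * sd_theory / sqrt(1000))
  expect_lt(abs(mean(pool$sbp) - (122 + 0.35 * 6.5 + 1.5)), 3 * 15 / sqrt(1000))
})

test_that("survey pool unit and degenerate cases behave", {
  one <- gen_survey_pool(1, seed = 2)
  expect_equal(nrow(one), 1)
  expect_true(one$sbp > 0 && one$total_chol > 0 && one$hdl > 0)
  expect_true(one$age >= 18 && one$age <= 95)
  none <- gen_survey_pool(500, seed = 2,
                          prevalence = list(smoking = 0, diabetes = 0.1,
                                            hypertension = 0.3,
                                            hyperlipidemia = 0.3))
  expect_false(any(none$smoking))
  expect_error(gen_survey_pool(0), class = "tractrisk_argument_error")
})

test_that("claim counts respect prevalence bounds and sampling noise", {
  tr <- gen_tract_lattice(8, 8, seed = 1)
  d <- gen_demographics(tr, mean_pop = 300, seed = 2)
  adults <- tractrisk:::claims_adults(d)
  zero <- gen_claims(tr, d, c(diabetes = 0), seed = 4)
  expect_true(all(zero$count == 0))
  full <- gen_claims(tr, d, c(diabetes = 1), seed = 4)
  expect_equal(full$count[match(adults$tract_id, full$tract_id)], adults$count)
  cl <- gen_claims(tr, d, c(diabetes = 0.15), seed = 4)
  expect_identical(cl, gen_claims(tr, d, c(diabetes = 0.15), seed = 4))
  frac <- cl$count[match(adults$tract_id, cl$tract_id)] / adults$count
  se <- sqrt(0.15 * 0.85 / mean(adults$count) / nrow(adults))
  expect_lt(abs(mean(frac) - 0.15), 3 * se)
  expect_error(gen_claims(tr, d, c(diabetes = 1.2)),
               class = "tractrisk_argument_error")
})

test_that("determinants are clamped, oriented and reproducible", {
  tr <- gen_tract_lattice(5, 5, seed = 1)
  det <- gen_determinants(tr, seed = 11)
  spec <- default_determinant_spec()
  for (k in seq_len(nrow(spec))) {
    x <- det[[spec$name[k]]]
    expect_true(all(x >= spec$min[k] & x <= spec$max[k]))
  }
  ori <- attr(det, "orientation")
  expect_setequal(names(ori), spec$name)
  expect_identical(det, gen_determinants(tr, seed = 11))
  expect_error(gen_determinants(tr, spatial_rho = 1),
               class = "tractrisk_argument_error")
})

test_that("null ground truth reproduces expected risk exactly", {
  sim <- make_small_world(seed = 31)
  null_truth <- ground_truth(determinant_effects = numeric(0), intercept = 0,
                             noise_sd = 0, seed = 31)
  deaths <- gen_observed_deaths(sim$expected, sim$demographics,
                                sim$determinants, null_truth, seed = 31,
                                realization = "fractional")
  obs <- observed_tract_rates(deaths, sim$demographics)
  m <- merge(sim$expected, obs, by = "tract_id")
  expect_equal(m$observed_per_100k, m$expected_per_100k, tolerance = 1e-9)

  rounded <- gen_observed_deaths(sim$expected, sim$demographics,
                                 sim$determinants, null_truth, seed = 31)
  expect_true(all(rounded$deaths == round(rounded$deaths)))
  obs_r <- observed_tract_rates(rounded, sim$demographics)
  m_r <- merge(sim$expected, obs_r, by = "tract_id")
  # integer rounding of band counts perturbs each tract rate by at most
  # 1e5 * sum_b w_b * 0.5 / pop_b (band-level quantization bound)
  pop_band <- aggregate(count ~ tract_id + age_band, sim$demographics, sum)
  std <- us2000_standard()
  bound <- vapply(m_r$tract_id, function(tid) {
    p <- pop_band[pop_band$tract_id == tid & pop_band$count > 0, ]
    w <- std[p$age_band] / sum(std[p$age_band])
    1e5 * sum(w * 0.5 / p$count)
  }, numeric(1))
  expect_true(all(abs(m_r$observed_per_100k - m_r$expected_per_100k) <=
                    bound + 1e-9))
})

test_that("noiseless planted slope is recovered by closed-form OLS", {
  sim <- make_small_world(seed = 32)
  truth <- ground_truth(determinant_effects = c(pct_food_stamps = -20),
                        intercept = 0, noise_sd = 0, seed = 32)
  deaths <- gen_observed_deaths(sim$expected, sim$demographics,
                                sim$determinants, truth, seed = 32,
                                realization = "fractional")
  obs <- observed_tract_rates(deaths, sim$demographics)
  m <- merge(sim$expected, obs, by = "tract_id")
  m <- merge(m, sim$determinants[, c("tract_id", "pct_food_stamps")],
             by = "tract_id")
  y <- m$expected_per_100k - m$observed_per_100k
  x <- m$pct_food_stamps
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(slope, -20, tolerance = 1e-9)
})

test_that("planted-slope coverage holds across noisy replicates", {
  sim <- make_small_world(seed = 33, n_rows = 6, n_cols = 6, mean_pop = 2000)
  truth <- ground_truth(determinant_effects = c(pct_food_stamps = -20),
                        intercept = 0, noise_sd = 200, spatial_rho = 0.3)
  covered <- vapply(1:60, function(r) {
    det <- gen_determinants(sim$tracts, spatial_rho = 0.3, seed = 5000 + r)
    deaths <- gen_observed_deaths(sim$expected, sim$demographics, det,
                                  truth, seed = 6000 + r)
    obs <- observed_tract_rates(deaths, sim$demographics)
    summ <- risk_difference(sim$expected, obs)
    fit <- multivariate_fit(summ, det, "pct_food_stamps")
    fit$terms$ci_lo[1] <= -20 && -20 <= fit$terms$ci_hi[1]
  }, logical(1))
  expect_gte(mean(covered), 0.9)
})

test_that("gen_observed_deaths validates its inputs", {
  sim <- make_small_world(seed = 34)
  truth <- ground_truth(seed = 34)
  expect_error(
    gen_observed_deaths(sim$expected, sim$demographics,
                        sim$determinants[-1, ], truth, seed = 1),
    class = "tractrisk_data_error")
  bad <- ground_truth(determinant_effects = c(not_a_column = 1), seed = 1)
  expect_error(
    gen_observed_deaths(sim$expected, sim$demographics, sim$determinants,
                        bad, seed = 1),
    class = "tractrisk_data_error")
  expect_error(ground_truth(noise_sd = -1), class = "tractrisk_argument_error")
})

test_that("a simulated bundle round-trips through its writers and readers", {
  sim <- make_small_world(seed = 35, n_rows = 2, n_cols = 3, mean_pop = 150)
  dir <- withr::local_tempdir()
  write_sim_dataset(sim, dir)
  expect_true(file.exists(file.path(dir, "truth.json")))
  back <- read_sim_dataset(dir)
  expect_identical(back$tracts$adjacency, sim$tracts$adjacency)
  expect_equal(back$tracts$tracts, sim$tracts$tracts)
  expect_equal(back$demographics, sim$demographics)
  expect_equal(back$claims, sim$claims)
  expect_equal(back$survey, sim$survey, tolerance = 1e-9)
  expect_equal(back$determinants, sim$determinants, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(attr(back$determinants, "orientation"),
               attr(sim$determinants, "orientation"))
  expect_equal(back$deaths, sim$deaths, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(unclass(back$truth), unclass(sim$truth))
  expect_equal(back$model$coefficients, sim$model$coefficients)
})
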