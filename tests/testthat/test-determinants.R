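summary_from <- function(diff, ids = sprintf("T%03d", seq_along(diff)),
                         pops = rep(1000, length(diff))) {
  structure(data.frame(tract_id = ids,
                       expected_per_100k = 1500,
                       observed_per_100k = 1500 - diff,
                       difference_per_100k = diff,
                       population = pops, stringsAsFactors = FALSE),
            class = c("tract_risk_summary", "data.frame"))
}

det_table <- function(...) {
  cols <- list(...)
  n <- length(cols[[1]])
  do.call(data.frame, c(list(tract_id = sprintf("T%03d", seq_len(n))), cols,
                        list(stringsAsFactors = FALSE)))
}

test_that("Pearson correlation matches hand computation and edge cases", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_correlation(x, 2 * x)$r, 1)
  expect_equal(pearson_correlation(x, -x)$r, -1)
  out <- pearson_correlation(x, c(1, 3, 2, 4))
  expect_equal(out$r, 0.8, tolerance = 1e-12)
  # p from the t transform with n - 2 df
  tval <- 0.8 * sqrt(2) / sqrt(1 - 0.64)
  expect_equal(out$p, 2 * pt(tval, 2, lower.tail = FALSE), tolerance = 1e-12)
  expect_error(pearson_correlation(x, rep(1, 4)),
               class = "tractrisk_stat_error")
  expect_error(pearson_correlation(1:2, 2:1),
               class = "tractrisk_argument_error")
})

test_that("the univariate screen applies the Bonferroni threshold over m", {
  set.seed(91)
  n <- 40
  diff <- rnorm(n)
  cols <- setNames(lapply(1:20, function(i) rnorm(n)), paste0("d", 1:20))
  det <- do.call(det_table, cols)
  scr <- univariate_screen(summary_from(diff), det)
  expect_equal(attr(scr, "m"), 20)
  expect_equal(attr(scr, "threshold"), 0.0025)
  expect_identical(scr$significant, scr$p_value < 0.0025)
  one <- univariate_screen(summary_from(diff), det[, c("tract_id", "d1")])
  expect_equal(attr(one, "threshold"), 0.05)
})

test_that("univariate slope and intercept match the normal equations", {
  s <- summary_from(c(1, 2, 4), ids = c("T001", "T002", "T003"))
  det <- det_table(x = c(0, 1, 2))
  scr <- univariate_screen(s, det)
  expect_equal(scr$slope, 1.5, tolerance = 1e-12)
  fit <- multivariate_fit(s, det, "x")
  expect_equal(fit$intercept, 5 / 6, tolerance = 1e-12)
})

test_that("screen skips constant or missing columns with a warning", {
  set.seed(92)
  s <- summary_from(rnorm(10))
  det <- det_table(good = rnorm(10), flat = rep(3, 10))
  expect_warning(scr <- univariate_screen(s, det), "constant")
  expect_equal(scr$determinant, "good")
  expect_equal(attr(scr, "m"), 1)
})

test_that("multivariate fits match the hand-coded OLS oracle", {
  set.seed(93)
  n <- 60
  x1 <- rnorm(n); x2 <- rnorm(n); x3 <- rnorm(n)
  y <- 2 + 1.5 * x1 - 0.8 * x2 + rnorm(n)
  s <- summary_from(y)
  det <- det_table(x1 = x1, x2 = x2, x3 = x3)
  fit <- multivariate_fit(s, det, c("x1", "x2", "x3"))
  oracle <- ols_oracle(cbind(x1, x2, x3), y)
  expect_equal(fit$terms$slope, unname(oracle$beta[-1]), tolerance = 1e-10)
  expect_equal(fit$terms$ci_lo, unname(oracle$ci_lo[-1]), tolerance = 1e-10)
  expect_equal(fit$terms$ci_hi, unname(oracle$ci_hi[-1]), tolerance = 1e-10)
  expect_equal(fit$terms$p_value, unname(oracle$p[-1]), tolerance = 1e-10)
  expect_equal(fit$adjusted_r2, oracle$adj_r2, tolerance = 1e-10)
  expect_equal(fit$residual_se, oracle$sigma, tolerance = 1e-10)
  # single-term call agrees with the univariate screen
  scr <- univariate_screen(s, det[, c("tract_id", "x1")])
  single <- multivariate_fit(s, det, "x1")
  expect_equal(single$terms$slope, scr$slope, tolerance = 1e-12)
  expect_equal(single$terms$p_value, scr$p_value, tolerance = 1e-12)
})

test_that("adjusted R2 follows its definition and perfect fits are exact", {
  set.seed(94)
  n <- 10
  x1 <- rnorm(n); x2 <- rnorm(n)
  y <- 3 * x1 - x2  # exact linear, no noise
  fit <- multivariate_fit(summary_from(y), det_table(x1 = x1, x2 = x2),
                          c("x1", "x2"))
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$residual_se, 0, tolerance = 1e-6)
  yr <- y + rnorm(n)
  fit2 <- multivariate_fit(summary_from(yr), det_table(x1 = x1, x2 = x2),
                           c("x1", "x2"))
  expect_equal(fit2$adjusted_r2,
               1 - (1 - fit2$r_squared) * (n - 1) / (n - 2 - 1),
               tolerance = 1e-12)
})

test_that("rank deficiency raises an error naming aliased terms", {
  set.seed(95)
  x1 <- rnorm(20)
  det <- det_table(x1 = x1, x2 = 2 * x1)
  expect_error(multivariate_fit(summary_from(rnorm(20)), det, c("x1", "x2")),
               "x2", class = "tractrisk_data_error")
})

test_that("backward stepwise keeps significant terms and logs a trace", {
  set.seed(96)
  n <- 80
  x1 <- rnorm(n); noise <- rnorm(n)
  y <- 5 * x1 + rnorm(n, 0, 0.5)
  s <- summary_from(y)
  det <- det_table(x1 = x1, noise = noise)
  out <- backward_stepwise(s, det, c("x1", "noise"))
  expect_equal(out$retained, "x1")
  expect_equal(nrow(out$trace), 2)
  expect_equal(out$trace$dropped[1], "noise")
  # all-significant candidate set is left untouched
  y2 <- 3 * x1 - 2 * noise + rnorm(n, 0, 0.3)
  out2 <- backward_stepwise(summary_from(y2), det, c("x1", "noise"))
  expect_setequal(out2$retained, c("x1", "noise"))
  expect_equal(nrow(out2$trace), 1)
})

test_that("stepwise elimination breaks exact ties by candidate order", {
  set.seed(97)
  n <- 30
  x1 <- rnorm(n)
  det <- det_table(a = x1, b = rev(x1))
  y <- rnorm(n)
  s <- summary_from(y)
  fit <- multivariate_fit(s, det, c("a", "b"))
  # force an artificial tie by checking the rule directly: when both
  # p-values exceed the threshold and are equal, the later candidate drops
  out <- backward_stepwise(s, det, c("a", "b"), p_remove = 1e-9)
  expect_equal(out$trace$dropped[1],
               fit$terms$name[which.max(fit$terms$p_value)])
  worst <- max(fit$terms$p_value)
  tied <- fit$terms$name[fit$terms$p_value == worst]
  if (length(tied) > 1) expect_equal(out$trace$dropped[1], tied[2])
})

test_that("stepwise recovers planted structure in simulation", {
  set.seed(98)
  n <- 100
  keep <- 0
  for (r in 1:50) {
    x <- rnorm(n); noise <- rnorm(n)
    y <- 1.2 * x + rnorm(n)
    out <- backward_stepwise(summary_from(y), det_table(x = x, noise = noise),
                             c("x", "noise"))
    keep <- keep + ("x" %in% out$retained && !"noise" %in% out$retained)
  }
  expect_gte(keep / 50, 0.85)
})

test_that("rank composite averages oriented ranks with average ties", {
  det <- det_table(a = c(10, 20, 30), b = c(5, 3, 1))
  ori <- c(a = "favorable_low", b = "favorable_low")
  rc <- rank_composite(det, c("a", "b"), orientation = ori)
  expect_equal(rc$mean_ranks$mean_rank, c((1 + 3) / 2, (2 + 2) / 2, (3 + 1) / 2))
  # orientation flip reverses ranks
  rc2 <- rank_composite(det, "a", orientation = c(a = "favorable_high"))
  expect_equal(rc2$mean_ranks$mean_rank, c(3, 2, 1))
  # ties get the average rank
  rc3 <- rank_composite(det_table(a = c(7, 7, 9)), "a",
                        orientation = c(a = "favorable_low"))
  expect_equal(rc3$mean_ranks$mean_rank, c(1.5, 1.5, 3))
  expect_error(rank_composite(det, c("a", "zz"), orientation = ori),
               class = "tractrisk_data_error")
  expect_error(rank_composite(det, "a", orientation = c(b = "favorable_low")),
               class = "tractrisk_config_error")
})

test_that("rank composite is invariant to monotone transforms", {
  set.seed(99)
  x <- runif(15, 1, 9)
  det1 <- det_table(a = x, b = rnorm(15))
  det2 <- det_table(a = exp(x), b = det1$b)
  ori <- c(a = "favorable_low", b = "favorable_low")
  rc1 <- rank_composite(det1, c("a", "b"), orientation = ori)
  rc2 <- rank_composite(det2, c("a", "b"), orientation = ori)
  expect_equal(rc1$mean_ranks, rc2$mean_ranks)
})

test_that("rank composite regression reports the slope on mean rank", {
  set.seed(100)
  n <- 30
  x <- runif(n, 0, 50)
  diff <- -12 * rank(x) + rnorm(n, 0, 5)
  s <- summary_from(diff)
  rc <- rank_composite(det_table(a = x), "a",
                       orientation = c(a = "favorable_low"), summary = s)
  expect_lt(rc$fit$terms$slope, 0)
  oracle <- ols_oracle(matrix(rank(x), ncol = 1), diff)
  expect_equal(rc$fit$terms$slope, unname(oracle$beta[2]), tolerance = 1e-10)
})
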