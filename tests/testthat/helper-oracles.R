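# Independent oracles used across test files.

# Hand-coded normal-equations OLS with t inference; independent of stats::lm.
ols_oracle <- function(X, y, level = 0.95) {
  X <- cbind(intercept = 1, as.matrix(X))
  n <- nrow(X); k <- ncol(X)
  XtX_inv <- solve(t(X) %*% X)
  beta <- drop(XtX_inv %*% t(X) %*% y)
  resid <- y - drop(X %*% beta)
  df <- n - k
  sigma2 <- sum(resid^2) / df
  se <- sqrt(diag(XtX_inv) * sigma2)
  tval <- beta / se
  p <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  tq <- stats::qt(1 - (1 - level) / 2, df)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- 1 - sum(resid^2) / ss_tot
  list(beta = beta, se = se, p = p,
       ci_lo = beta - tq * se, ci_hi = beta + tq * se,
       r2 = r2, adj_r2 = 1 - (1 - r2) * (n - 1) / (n - k),
       sigma = sqrt(sigma2), n = n)
}

# Brute-force O(n^2) Moran's I from a dense row-standardized weight matrix.
moran_oracle <- function(values, W) {
  z <- values - mean(values)
  n <- length(z)
  s0 <- 0; acc <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      s0 <- s0 + W[i, j]
      acc <- acc + W[i, j] * z[i] * z[j]
    }
  }
  (n / s0) * acc / sum(z^2)
}

# Dense row-standardized rook weight matrix for an r x c lattice, built
# directly from lattice coordinates (independent of build_weights).
lattice_rook_W <- function(r, c) {
  n <- r * c
  row <- (seq_len(n) - 1L) %/% c + 1L
  col <- (seq_len(n) - 1L) %% c + 1L
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nb <- which(abs(row - row[i]) + abs(col - col[i]) == 1)
    W[i, nb] <- 1 / length(nb)
  }
  W
}

# A small complete input bundle shared by integration-style tests.
make_small_world <- function(seed = 2024, n_rows = 4, n_cols = 4,
                             mean_pop = 400, survey_n = 1500, ...) {
  simulate_inputs(n_rows, n_cols, seed = seed, mean_pop = mean_pop,
                  survey_n = survey_n, ...)
}

# Donor pool with exactly one donor per (sex, adult band), deterministic
# biomarkers encoding the stratum, for strict hot-deck identity checks.
one_donor_pool <- function() {
  bands <- age_bands()[4:18]  # 15-19 through 85+
  mid <- tractrisk:::band_lower(bands) + 2
  pool <- expand.grid(band_i = seq_along(bands), sex = c("male", "female"),
                      stringsAsFactors = FALSE)
  data.frame(
    age = mid[pool$band_i],
    sex = pool$sex,
    smoking = pool$band_i %% 2 == 0,
    diabetes = FALSE, hypertension = FALSE, hyperlipidemia = FALSE,
    sbp = 100 + pool$band_i + 50 * (pool$sex == "male"),
    total_chol = 150 + pool$band_i,
    hdl = 40 + pool$band_i,
    stringsAsFactors = FALSE)
}
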