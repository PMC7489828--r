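# Association of the tract excess-risk difference with social and biological
# determinants: Pearson correlations, Bonferroni-corrected univariate OLS,
# multivariate OLS with backward stepwise elimination, and the rank
# composite.

#' Two-tailed Pearson correlation
#'
#' @param x,y numeric vectors of equal length, at least 3, nonconstant.
#' @return list with `r` and `p` (two-sided, t transform on n - 2 df).
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) abort_arg("`x` and `y` must have equal length")
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) abort_arg("need at least 3 complete pairs")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    abort_stat("correlation is undefined for constant input")
  }
  ct <- stats::cor.test(x, y, alternative = "two.sided", method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

# Merge a tract_risk_summary with a determinant table by tract_id.
merge_summary <- function(summary, determinants,
                          response = "difference_per_100k") {
  if (!response %in% names(summary)) {
    abort_arg(sprintf("summary lacks response column `%s`", response))
  }
  merge(as.data.frame(summary)[, c("tract_id", response)], determinants,
        by = "tract_id", sort = TRUE)
}

#' Univariate regression screen with Bonferroni correction
#'
#' Regresses the tract difference on each determinant separately; a
#' determinant is flagged significant when its slope p-value falls below
#' `alpha / m`, where `m` is the number of determinants actually screened
#' (all-missing or constant columns are skipped with a warning but still
#' reported as skipped).
#'
#' @param summary a `tract_risk_summary` (or data frame with the response).
#' @param determinants determinant table (`tract_id` + one column per
#'   determinant).
#' @param alpha familywise significance level (default 0.05).
#' @param response response column (default `difference_per_100k`).
#' @return data frame (class `univariate_screen`) with one row per screened
#'   determinant: `determinant`, `slope`, `ci_lo`, `ci_hi`, `p_value`, `n`,
#'   `significant`; attributes `threshold`, `m`, `alpha`.
#' @export
univariate_screen <- function(summary, determinants, alpha = 0.05,
                              response = "difference_per_100k") {
  m0 <- merge_summary(summary, determinants, response)
  dets <- setdiff(names(determinants), "tract_id")
  usable <- character(0)
  for (d in dets) {
    x <- m0[[d]]
    if (all(is.na(x)) || stats::var(x, na.rm = TRUE) == 0) {
      warning(sprintf("skipping determinant `%s` (all missing or constant)", d),
              call. = FALSE)
    } else if (sum(stats::complete.cases(x, m0[[response]])) >= 3) {
      usable <- c(usable, d)
    } else {
      warning(sprintf("skipping determinant `%s` (fewer than 3 complete cases)", d),
              call. = FALSE)
    }
  }
  m <- length(usable)
  if (m == 0) abort_data("no usable determinant columns to screen")
  threshold <- alpha / m
  rows <- lapply(usable, function(d) {
    df <- m0[stats::complete.cases(m0[[d]], m0[[response]]), ]
    fit <- stats::lm(stats::reformulate(d, response), data = df)
    ci <- suppressWarnings(stats::confint(fit))
    sm <- suppressWarnings(stats::summary.lm(fit))
    data.frame(determinant = d,
               slope = unname(stats::coef(fit)[2]),
               ci_lo = ci[2, 1], ci_hi = ci[2, 2],
               p_value = sm$coefficients[2, 4],
               n = nrow(df),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$significant <- out$p_value < threshold
  rownames(out) <- NULL
  attr(out, "threshold") <- threshold
  attr(out, "m") <- m
  attr(out, "alpha") <- alpha
  class(out) <- c("univariate_screen", "data.frame")
  out
}

#' Multivariate OLS of the tract difference on named determinants
#'
#' Complete-case ordinary least squares with per-term 95% confidence
#' intervals and p-values, adjusted R-squared
#' `1 - (1 - R^2)(n - 1)/(n - k - 1)` and residual standard error. A
#' rank-deficient design is an error naming the aliased terms.
#'
#' @param summary a `tract_risk_summary`.
#' @param determinants determinant table.
#' @param terms character vector of determinant names to include.
#' @param response response column (default `difference_per_100k`).
#' @return object of class `regression_result`: list with `terms` (data
#'   frame: `name`, `slope`, `ci_lo`, `ci_hi`, `p_value`), `intercept`,
#'   `r_squared`, `adjusted_r2`, `residual_se`, `n`, `response`.
#' @export
multivariate_fit <- function(summary, determinants, terms,
                             response = "difference_per_100k") {
  if (length(terms) < 1) abort_arg("`terms` must name at least one determinant")
  missing_terms <- setdiff(terms, names(determinants))
  if (length(missing_terms) > 0) {
    abort_data(sprintf("determinant column(s) not found: %s",
                       paste(missing_terms, collapse = ", ")))
  }
  m0 <- merge_summary(summary, determinants, response)
  df <- m0[stats::complete.cases(m0[, c(response, terms)]), , drop = FALSE]
  if (nrow(df) < length(terms) + 2) {
    abort_arg("too few complete cases for the requested terms")
  }
  X <- as.matrix(df[, terms, drop = FALSE])
  if (qr(cbind(1, X))$rank < length(terms) + 1) {
    al <- stats::alias(stats::lm(
      stats::reformulate(terms, response), data = df))
    aliased <- rownames(al$Complete) %||% "unknown"
    abort_data(sprintf("rank-deficient design; aliased term(s): %s",
                       paste(aliased, collapse = ", ")))
  }
  fit <- stats::lm(stats::reformulate(terms, response), data = df)
  sm <- suppressWarnings(stats::summary.lm(fit))
  ci <- suppressWarnings(stats::confint(fit))
  k <- length(terms)
  tab <- data.frame(name = terms,
                    slope = unname(stats::coef(fit)[terms]),
                    ci_lo = ci[terms, 1], ci_hi = ci[terms, 2],
                    p_value = sm$coefficients[terms, 4],
                    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  structure(list(terms = tab,
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = sm$r.squared,
                 adjusted_r2 = sm$adj.r.squared,
                 residual_se = sm$sigma,
                 n = nrow(df), response = response),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("OLS of %s on %d term(s), n = %d tracts\n",
              x$response, nrow(x$terms), x$n))
  for (i in seq_len(nrow(x$terms))) {
    cat(sprintf("  %-24s %10.4g (%.4g to %.4g)  p = %.3g\n",
                x$terms$name[i], x$terms$slope[i], x$terms$ci_lo[i],
                x$terms$ci_hi[i], x$terms$p_value[i]))
  }
  cat(sprintf("  adjusted R2 = %.3f; residual SE = %.4g\n",
              x$adjusted_r2, x$residual_se))
  invisible(x)
}

#' Backward stepwise elimination on p-values
#'
#' Starting from the full model over `candidates`, iteratively refits after
#' dropping the term with the largest p-value above `p_remove`; stops when
#' every retained term has p at or below `p_remove` or a single term remains.
#' Ties on p are broken by dropping the term that appears later in the
#' candidate order.
#'
#' @param summary a `tract_risk_summary`.
#' @param determinants determinant table.
#' @param candidates character vector of candidate determinant names.
#' @param p_remove removal threshold (default 0.05).
#' @param response response column.
#' @return list with `retained` (character), `fit` (final
#'   [multivariate_fit()] result) and `trace` (data frame: one row per step
#'   with the terms, adjusted R-squared, and the dropped term).
#' @export
backward_stepwise <- function(summary, determinants, candidates,
                              p_remove = 0.05,
                              response = "difference_per_100k") {
  if (length(candidates) < 1) abort_arg("need at least one candidate term")
  current <- candidates
  trace <- list()
  step <- 0L
  repeat {
    step <- step + 1L
    fit <- multivariate_fit(summary, determinants, current, response)
    p <- fit$terms$p_value
    worst <- max(p)
    drop_term <- NA_character_
    if (worst > p_remove && length(current) > 1) {
      # later candidate-order position wins ties
      tied <- fit$terms$name[p == worst]
      drop_term <- tied[which.max(match(tied, candidates))]
    }
    trace[[step]] <- data.frame(step = step,
                                terms = paste(current, collapse = "+"),
                                adjusted_r2 = fit$adjusted_r2,
                                dropped = drop_term,
                                stringsAsFactors = FALSE)
    if (is.na(drop_term)) break
    current <- setdiff(current, drop_term)
  }
  list(retained = current, fit = fit, trace = do.call(rbind, trace))
}

#' Rank composite of determinants
#'
#' Within each determinant, tracts are ranked 1 (most favorable) to n (least
#' favorable) honoring the determinant's orientation, with ties receiving the
#' average rank; the composite is the mean rank across the chosen subset.
#' When a tract summary is supplied, the difference is regressed on the mean
#' rank (a negative slope means less favorable tracts carry more excess
#' risk).
#'
#' @param determinants determinant table; orientations are taken from its
#'   `orientation` attribute unless given explicitly.
#' @param subset determinant names to include (nonempty).
#' @param orientation named character vector mapping each subset determinant
#'   to `"favorable_high"` or `"favorable_low"`.
#' @param summary optional `tract_risk_summary` for the regression.
#' @param response response column.
#' @return list with `mean_ranks` (data frame `tract_id`, `mean_rank`),
#'   `ranks` (per-determinant rank matrix) and, when `summary` is given,
#'   `fit` (a [multivariate_fit()]-style regression of difference on mean
#'   rank).
#' @export
rank_composite <- function(determinants, subset,
                           orientation = attr(determinants, "orientation"),
                           summary = NULL,
                           response = "difference_per_100k") {
  if (length(subset) < 1) abort_arg("`subset` must name at least one determinant")
  missing_cols <- setdiff(subset, names(determinants))
  if (length(missing_cols) > 0) {
    abort_data(sprintf("determinant column(s) not found: %s",
                       paste(missing_cols, collapse = ", ")))
  }
  unoriented <- subset[!subset %in% names(orientation) |
                         !orientation[subset] %in% c("favorable_high",
                                                     "favorable_low")]
  if (length(unoriented) > 0) {
    abort_config(sprintf("no orientation for determinant(s): %s",
                         paste(unoriented, collapse = ", ")))
  }
  ranks <- sapply(subset, function(d) {
    x <- determinants[[d]]
    if (orientation[[d]] == "favorable_high") {
      rank(-x, ties.method = "average")
    } else {
      rank(x, ties.method = "average")
    }
  })
  ranks <- matrix(ranks, nrow = nrow(determinants),
                  dimnames = list(NULL, subset))
  mr <- data.frame(tract_id = determinants$tract_id,
                   mean_rank = rowMeans(ranks),
                   stringsAsFactors = FALSE)
  out <- list(mean_ranks = mr, ranks = ranks)
  if (!is.null(summary)) {
    out$fit <- multivariate_fit(summary, mr, "mean_rank", response = response)
  }
  out
}
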