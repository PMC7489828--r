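# Internal helpers: classed errors, scoped RNG, age-band arithmetic, file IO.

abort_arg <- function(msg, call. = FALSE) {
  stop(errorCondition(msg, class = c("tractrisk_argument_error", "tractrisk_error")))
}

abort_data <- function(msg) {
  stop(errorCondition(msg, class = c("tractrisk_data_error", "tractrisk_error")))
}

abort_config <- function(msg) {
  stop(errorCondition(msg, class = c("tractrisk_config_error", "tractrisk_error")))
}

abort_stat <- function(msg) {
  stop(errorCondition(msg, class = c("tractrisk_stat_error", "tractrisk_error")))
}

#' Evaluate an expression under a local RNG seed
#'
#' Runs `expr` with the global RNG seeded to `seed` and restores the previous
#' RNG state afterwards, so package generators never disturb the caller's
#' random stream. All exported generators funnel their randomness through this.
#'
#' @param seed single integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (length(seed) != 1L || !is.finite(seed)) {
    abort_arg("`seed` must be a single finite integer")
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic sub-seed derivation so one master seed drives several
# independent generator calls without reuse. Kept below 2^31.
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(offset) %% 1000L
}

#' Five-year age bands used throughout the pipeline
#'
#' The 18 standard five-year census bands from 0-4 through 85+. Every
#' demographic table, death-count table and baseline-survival table in the
#' package is keyed on these labels.
#'
#' @return character vector of 18 band labels.
#' @export
#' @examples
#' age_bands()
age_bands <- function() {
  c(paste(seq(0, 80, by = 5), seq(4, 84, by = 5), sep = "-"), "85+")
}

# Lower bound of each band in years.
band_lower <- function(bands = age_bands()) {
  lower <- rep(85, length(bands))
  plain <- bands != "85+"
  lower[plain] <- as.numeric(sub("-.*", "", bands[plain]))
  lower
}

# Width of the uniform age draw within a band; the open-ended band spans
# 85-100 by convention.
band_width <- function(bands = age_bands()) {
  ifelse(bands == "85+", 15, 5)
}

#' Map exact ages to five-year band labels
#'
#' @param age numeric vector of ages in years.
#' @return character vector of band labels from [age_bands()].
#' @export
band_of_age <- function(age) {
  if (any(!is.finite(age)) || any(age < 0)) {
    abort_arg("`age` must be finite and nonnegative")
  }
  idx <- pmin(findInterval(age, seq(0, 85, by = 5)), 18L)
  age_bands()[idx]
}

# ---- tabular IO -------------------------------------------------------------

provenance_line <- function(seed = NULL) {
  ver <- as.character(utils::packageVersion("tractrisk"))
  if (is.null(seed)) {
    sprintf("# tractrisk %s", ver)
  } else {
    sprintf("# tractrisk %s seed=%d", ver, as.integer(seed))
  }
}

#' Write a data frame as headered CSV with a provenance comment line
#'
#' @param df data frame.
#' @param path output path.
#' @param seed optional seed recorded in the provenance line.
#' @return `path`, invisibly.
#' @export
write_tract_csv <- function(df, path, seed = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(provenance_line(seed), con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a CSV written by [write_tract_csv()]
#'
#' Comment lines starting with `#` are skipped.
#'
#' @param path input path.
#' @return data frame.
#' @export
read_tract_csv <- function(path) {
  if (!file.exists(path)) abort_data(sprintf("file not found: %s", path))
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
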