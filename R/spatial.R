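# Contiguity spatial weights and global Moran's I with a permutation
# pseudo-p, for testing spatial clustering of the excess-risk surface.

#' Build row-standardized contiguity weights from a tract set
#'
#' Rook weights use the tract set's stored edge-sharing adjacency; queen
#' weights add diagonal contiguity, derived from the lattice row/column
#' coordinates. Rows of tracts with at least one neighbor sum to 1; islands
#' (no neighbors) keep zero rows and are flagged.
#'
#' @param tracts a `tract_set`, or a named list of neighbor id vectors
#'   (rook scheme only).
#' @param scheme `"rook"` (default) or `"queen"`.
#' @return object of class `spatial_weights`: list with `ids`, `neighbors`
#'   (list of integer indices), `weights` (list of numeric weights) and
#'   `islands` (character ids).
#' @export
build_weights <- function(tracts, scheme = c("rook", "queen")) {
  scheme <- match.arg(scheme)
  if (inherits(tracts, "tract_set")) {
    ids <- tracts$tracts$tract_id
    if (scheme == "rook") {
      adj <- tracts$adjacency
    } else {
      row <- tracts$tracts$row
      col <- tracts$tracts$col
      adj <- lapply(seq_along(ids), function(i) {
        nb <- which(pmax(abs(row - row[i]), abs(col - col[i])) == 1)
        ids[nb]
      })
      names(adj) <- ids
    }
  } else if (is.list(tracts) && !is.null(names(tracts))) {
    if (scheme == "queen") {
      abort_arg("queen contiguity requires lattice geometry; got an adjacency list")
    }
    ids <- names(tracts)
    adj <- tracts
  } else {
    abort_arg("`tracts` must be a tract_set or a named adjacency list")
  }
  nb_idx <- lapply(ids, function(id) {
    j <- match(adj[[id]], ids)
    if (any(is.na(j))) abort_data(sprintf("unknown neighbor id for tract %s", id))
    sort(j)
  })
  names(nb_idx) <- ids
  # symmetry and irreflexivity checks
  for (i in seq_along(ids)) {
    if (i %in% nb_idx[[i]]) abort_data(sprintf("tract %s is its own neighbor", ids[i]))
    for (j in nb_idx[[i]]) {
      if (!(i %in% nb_idx[[j]])) {
        abort_data(sprintf("asymmetric adjacency between %s and %s",
                           ids[i], ids[j]))
      }
    }
  }
  islands <- ids[lengths(nb_idx) == 0]
  if (length(islands) > 0) {
    warning(sprintf("%d island tract(s) with no neighbors: %s",
                    length(islands), paste(islands, collapse = ", ")),
            call. = FALSE)
  }
  w <- lapply(nb_idx, function(nb) {
    if (length(nb) == 0) numeric(0) else rep(1 / length(nb), length(nb))
  })
  structure(list(ids = ids, neighbors = nb_idx, weights = w,
                 islands = islands, scheme = scheme),
            class = "spatial_weights")
}

# Dense weights matrix over the non-island subset, with the ids kept.
weights_dense <- function(w) {
  keep <- which(!(w$ids %in% w$islands))
  pos <- match(seq_along(w$ids), keep)
  n <- length(keep)
  W <- matrix(0, n, n)
  for (ii in seq_len(n)) {
    i <- keep[ii]
    nb <- w$neighbors[[i]]
    ok <- !is.na(pos[nb])
    W[ii, pos[nb[ok]]] <- w$weights[[i]][ok]
  }
  # re-standardize rows in case an island neighbor was dropped
  rs <- rowSums(W)
  W[rs > 0, ] <- W[rs > 0, , drop = FALSE] / rs[rs > 0]
  list(W = W, keep = keep, ids = w$ids[keep])
}

#' Global Moran's I
#'
#' `I = (n / S0) * sum_ij w_ij z_i z_j / sum_i z_i^2` with `z` the deviations
#' from the mean and `S0` the total weight. Island tracts are excluded from
#' the statistic. Constant values make the statistic undefined and raise an
#' error rather than returning 0.
#'
#' @param values numeric vector aligned to `w$ids`.
#' @param w a [build_weights()] object.
#' @return Moran's I (scalar).
#' @export
morans_i <- function(values, w) {
  stopifnot(inherits(w, "spatial_weights"))
  if (length(values) != length(w$ids)) {
    abort_arg("`values` must align with the weights' tract ids")
  }
  if (any(!is.finite(values))) abort_arg("`values` must be finite")
  d <- weights_dense(w)
  x <- values[d$keep]
  if (stats::var(x) == 0) {
    abort_stat("Moran's I is undefined for constant values")
  }
  z <- x - mean(x)
  n <- length(z)
  s0 <- sum(d$W)
  (n / s0) * sum(z * (d$W %*% z)) / sum(z^2)
}

#' Permutation test for global Moran's I
#'
#' Values are randomly reassigned to tracts `n_permutations` times; the
#' pseudo-p is `(1 + #{permuted I >= observed I}) / (n_permutations + 1)`
#' under the default `alternative = "greater"` (spatial clustering, the
#' alternative of interest for an excess-risk surface). `"less"` tests
#' dispersion; `"folded"` counts permutations at least as extreme as the
#' observed deviation from the null expectation `-1/(n-1)`, on the observed
#' side. The z-score is the observed I standardized by the permutation
#' distribution.
#'
#' @param values numeric vector aligned to `w$ids`.
#' @param w a [build_weights()] object.
#' @param n_permutations number of permutations (default 999).
#' @param seed integer seed.
#' @param alternative `"greater"` (default), `"less"` or `"folded"`.
#' @return object of class `moran_result`: list with `I`, `expected_I`,
#'   `pseudo_p`, `z`, `n_permutations`, `n`, `alternative`, `seed`.
#' @export
morans_permutation <- function(values, w, n_permutations = 999, seed = 1L,
                               alternative = c("greater", "less", "folded")) {
  alternative <- match.arg(alternative)
  if (length(n_permutations) != 1L || n_permutations < 1) {
    abort_arg("`n_permutations` must be a positive integer")
  }
  stopifnot(inherits(w, "spatial_weights"))
  if (length(values) != length(w$ids)) {
    abort_arg("`values` must align with the weights' tract ids")
  }
  d <- weights_dense(w)
  x <- values[d$keep]
  if (stats::var(x) == 0) {
    abort_stat("Moran's I is undefined for constant values")
  }
  z <- x - mean(x)
  n <- length(z)
  s0 <- sum(d$W)
  ss <- sum(z^2)
  i_obs <- (n / s0) * sum(z * (d$W %*% z)) / ss
  perm <- with_seed(seed, {
    Z <- vapply(seq_len(n_permutations), function(k) z[sample.int(n)],
                numeric(n))
    (n / s0) * colSums(Z * (d$W %*% Z)) / ss
  })
  e_i <- -1 / (n - 1)
  pseudo_p <- switch(alternative,
    greater = (1 + sum(perm >= i_obs)) / (n_permutations + 1),
    less = (1 + sum(perm <= i_obs)) / (n_permutations + 1),
    folded = if (i_obs >= e_i) {
      (1 + sum(perm >= i_obs)) / (n_permutations + 1)
    } else {
      (1 + sum(perm <= i_obs)) / (n_permutations + 1)
    })
  structure(list(I = i_obs, expected_I = e_i, pseudo_p = pseudo_p,
                 z = (i_obs - mean(perm)) / stats::sd(perm),
                 perm_mean = mean(perm), perm_sd = stats::sd(perm),
                 n_permutations = as.integer(n_permutations), n = n,
                 alternative = alternative, islands = w$islands,
                 seed = as.integer(seed)),
            class = "moran_result")
}

#' @export
print.moran_result <- function(x, ...) {
  cat(sprintf("Global Moran's I: %.3f (E[I] = %.4f, n = %d)\n",
              x$I, x$expected_I, x$n))
  cat(sprintf("  pseudo p = %.4g (%s, %d permutations); z = %.2f\n",
              x$pseudo_p, x$alternative, x$n_permutations, x$z))
  if (length(x$islands) > 0) {
    cat(sprintf("  excluded islands: %s\n", paste(x$islands, collapse = ", ")))
  }
  invisible(x)
}
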