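# Level metrics and the monotonicity theory of the conditional response
# probabilities.

#' Level metrics
#'
#' A level metric is a symmetric nonnegative table of dissimilarities between
#' response levels with zero diagonal and positive off-diagonal entries.
#' The triangle inequality and the order-respecting property are *not*
#' enforced at construction; they are checked on demand with
#' [check_metric_axioms()] and [is_order_respecting()], since useful
#' dissimilarity tables (including textbook examples) may violate them.
#'
#' `hamming_metric()` is 0 on the diagonal and 1 elsewhere: the only
#' meaningful metric when levels are unordered, under which delta-monotonicity
#' reduces to modality. `manhattan_metric()` is `|i - j|` in level-code
#' units, the discrete Manhattan distance (the size of the symmetric
#' difference of the two down sets on the chain).
#'
#' @param dist square numeric matrix of level dissimilarities.
#' @param n_levels number of levels of the chain.
#' @return A `level_metric`: the validated matrix.
#' @examples
#' manhattan_metric(4)
#' @export
level_metric <- function(dist) {
  dist <- as.matrix(dist)
  if (nrow(dist) != ncol(dist)) stop_input("metric matrix must be square")
  if (any(dist < 0)) stop_input("distances must be nonnegative")
  if (any(diag(dist) != 0)) stop_input("metric diagonal must be zero")
  if (!isTRUE(all.equal(dist, t(dist)))) stop_input("metric must be symmetric")
  off <- dist[row(dist) != col(dist)]
  if (any(off <= 0)) stop_input("off-diagonal distances must be positive")
  structure(unname(dist), class = c("level_metric", "matrix", "array"))
}

#' @rdname level_metric
#' @export
hamming_metric <- function(n_levels) {
  level_metric(1 - diag(n_levels))
}

#' @rdname level_metric
#' @export
manhattan_metric <- function(n_levels) {
  idx <- seq_len(n_levels) - 1L
  level_metric(abs(outer(idx, idx, "-")))
}

#' Check the metric axioms of a level dissimilarity table
#'
#' Exhaustively verifies identity of indiscernibles, symmetry and the
#' triangle inequality over all level triples, returning witnesses for any
#' failure.
#'
#' @param metric a [level_metric] (or plain square matrix).
#' @return A list with logical elements `identity`, `symmetry`, `triangle`
#'   and a matrix `triangle_witnesses` of violating triples (0-based level
#'   codes `i, k, j` with `dist(i, j) > dist(i, k) + dist(k, j)`).
#' @export
check_metric_axioms <- function(metric) {
  d <- as.matrix(metric)
  L <- nrow(d)
  identity_ok <- all(diag(d) == 0) &&
    all(d[row(d) != col(d)] > 0)
  symmetry_ok <- isTRUE(all.equal(d, t(d), check.attributes = FALSE))
  wit <- NULL
  for (i in seq_len(L)) {
    for (k in seq_len(L)) {
      bad <- which(d[i, ] > d[i, k] + d[k, ] + 1e-12)
      if (length(bad)) {
        wit <- rbind(wit, cbind(i - 1L, k - 1L, bad - 1L))
      }
    }
  }
  list(
    identity = identity_ok,
    symmetry = symmetry_ok,
    triangle = is.null(wit),
    triangle_witnesses = if (is.null(wit)) {
      matrix(integer(0), 0L, 3L, dimnames = list(NULL, c("i", "via", "j")))
    } else {
      colnames(wit) <- c("i", "via", "j")
      unique(wit)
    }
  )
}

#' Is a level metric order respecting?
#'
#' On a chain of levels, a metric is order respecting when distances grow
#' strictly along the order: `i < j < k` implies
#' `dist(i, k) > max(dist(i, j), dist(j, k))`.
#'
#' @param metric a [level_metric].
#' @return Logical with attribute `witnesses`: violating increasing triples
#'   (0-based codes).
#' @export
is_order_respecting <- function(metric) {
  d <- as.matrix(metric)
  L <- nrow(d)
  wit <- NULL
  if (L >= 3L) {
    for (i in 1:(L - 2L)) {
      for (j in (i + 1L):(L - 1L)) {
        for (k in (j + 1L):L) {
          if (d[i, k] <= max(d[i, j], d[j, k])) {
            wit <- rbind(wit, c(i, j, k) - 1L)
          }
        }
      }
    }
  }
  out <- is.null(wit)
  if (!out) colnames(wit) <- c("i", "j", "k")
  attr(out, "witnesses") <- wit
  out
}

#' Same-side level triples used by half-monotonicity
#'
#' Half-monotonicity restricts the monotonicity condition to triples
#' `(i, j, k)` in which `j` and `k` lie on one side of `i`:
#' `i <= min(j, k)` or `max(j, k) < i` (the upper bound strict; with this
#' convention a 4-level chain yields the reference count of 44 triples out
#' of 64).
#'
#' @param n_levels number of levels of the chain.
#' @return Integer matrix of triples (columns `i`, `j`, `k`, 0-based codes).
#' @examples
#' nrow(restricted_triples(4)) # 44
#' @export
restricted_triples <- function(n_levels) {
  idx <- seq_len(n_levels) - 1L
  g <- expand.grid(k = idx, j = idx, i = idx)[, 3:1]
  keep <- (g$i <= pmin(g$j, g$k)) | (pmax(g$j, g$k) < g$i)
  out <- as.matrix(g[keep, c("i", "j", "k")])
  dimnames(out) <- list(NULL, c("i", "j", "k"))
  out
}

# Shared engine: test the biconditional
#   dist(i,j) < dist(i,k)  <=>  f(i,j) > f(i,k)
# over the given triples. Tied distances impose no constraint (both
# orderings of j, k are always in the triple set, so strict inequalities in
# either direction are fully tested); tied f values under strictly ordered
# distances falsify the condition. Triples touching an undefined f value
# are skipped.
check_monotone_triples <- function(f, metric, triples) {
  f <- as.matrix(f)
  d <- as.matrix(metric)
  i <- triples[, 1L] + 1L
  j <- triples[, 2L] + 1L
  k <- triples[, 3L] + 1L
  fij <- f[cbind(i, j)]
  fik <- f[cbind(i, k)]
  defined <- !is.na(fij) & !is.na(fik)
  dij <- d[cbind(i, j)]
  dik <- d[cbind(i, k)]
  viol <- defined & ((dij < dik & fij <= fik) | (dij > dik & fij >= fik))
  res <- structure(!any(viol), class = "monotonicity_check")
  attr(res, "violations") <- triples[viol, , drop = FALSE]
  attr(res, "n_checked") <- sum(defined)
  attr(res, "n_skipped") <- sum(!defined)
  res
}

#' @export
print.monotonicity_check <- function(x, ...) {
  cat(
    "Monotonicity check: ", if (x) "PASS" else "FAIL", " (",
    attr(x, "n_checked"), " triples checked, ",
    attr(x, "n_skipped"), " skipped)\n",
    sep = ""
  )
  v <- attr(x, "violations")
  if (nrow(v)) {
    cat("violating triples (i, j, k):\n")
    print(utils::head(v, 10L))
  }
  invisible(x)
}

#' Delta-monotonicity and half-monotonicity of a pair function
#'
#' A function `f` on level pairs is delta-monotone for a metric `delta` when
#' `delta(i, j) < delta(i, k)` iff `f(i, j) > f(i, k)` for all level triples:
#' values decay strictly with distance from `i`. It is delta-half-monotone
#' when the biconditional holds on the same-side triples of
#' [restricted_triples()] only. Applied to the rows of an error matrix, full
#' Manhattan monotonicity requires decay across the diagonal, while
#' half-monotonicity only requires unimodal decay on each side.
#'
#' Partial pair functions are supported: triples touching an undefined (`NA`)
#' value are skipped and counted.
#'
#' @param f square numeric matrix (possibly with `NA` entries): `f[i, j]` is
#'   the value at level pair `(i, j)`, 0-based codes.
#' @param metric a [level_metric].
#' @return Logical of class `monotonicity_check` with attributes
#'   `violations` (matrix of violating triples, 0-based), `n_checked`,
#'   `n_skipped`.
#' @examples
#' f <- matrix(NA_real_, 5, 5)
#' f[3, ] <- epsilon_row_from_rates(upsilon = c(.2, .1), omega = c(.3, .5))
#' is_delta_half_monotone(f, manhattan_metric(5))
#' @export
is_delta_monotone <- function(f, metric) {
  L <- nrow(as.matrix(metric))
  idx <- seq_len(L) - 1L
  g <- expand.grid(k = idx, j = idx, i = idx)[, 3:1]
  triples <- as.matrix(g)
  dimnames(triples) <- list(NULL, c("i", "j", "k"))
  check_monotone_triples(f, metric, triples)
}

#' @rdname is_delta_monotone
#' @export
is_delta_half_monotone <- function(f, metric) {
  L <- nrow(as.matrix(metric))
  check_monotone_triples(f, metric, restricted_triples(L))
}

#' Modality and overall-error conditions on an error matrix
#'
#' `check_modality()` tests that the true level is modal in every row:
#' `eps(i, i) > eps(i, j)` for all `j != i` (equivalently, Hamming-metric
#' monotonicity). `check_overall_error()` tests the stronger condition that
#' each diagonal entry exceeds the sum of the other entries in its row
#' (which forces the diagonal above 1/2).
#'
#' @param E square row-stochastic error matrix.
#' @return Logical with attribute `rows`: the per-row verdicts.
#' @examples
#' E <- matrix(c(.9, .1, .2, .8), 2, byrow = TRUE)
#' check_modality(E)
#' check_overall_error(E)
#' @export
check_modality <- function(E) {
  E <- as.matrix(E)
  rows <- vapply(seq_len(nrow(E)), function(i) {
    all(E[i, i] > E[i, -i])
  }, logical(1))
  structure(all(rows), rows = rows)
}

#' @rdname check_modality
#' @export
check_overall_error <- function(E) {
  E <- as.matrix(E)
  rows <- vapply(seq_len(nrow(E)), function(i) {
    E[i, i] > sum(E[i, -i])
  }, logical(1))
  structure(all(rows), rows = rows)
}

#' Column view of an item's error matrix
#'
#' Returns the transposed error matrix of one item, so that every row
#' monotonicity checker doubles as a column checker: column monotonicity of
#' `eps_q` is row monotonicity of `t(eps_q)`.
#'
#' @param params a [polim_params] object (or a single error matrix).
#' @param item item identifier or index.
#' @return The transposed error matrix (a pair function).
#' @export
column_view <- function(params, item = NULL) {
  E <- if (is.matrix(params)) params else params$epsilon[[item]]
  t(as.matrix(E))
}
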