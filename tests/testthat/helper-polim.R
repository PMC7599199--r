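# Shared fixture builders: everything is generated in code.

# Diagonal-dominant error matrix with the remaining mass spread unevenly.
dominant_error_matrix <- function(L, diag_val = 0.9) {
  E <- matrix(0, L, L)
  for (i in seq_len(L)) {
    off <- rev(seq_len(L - 1))
    off <- off / sum(off) * (1 - diag_val)
    E[i, -i] <- off
    E[i, i] <- diag_val
  }
  E
}

# Random row-stochastic matrices / simplex points (flat Dirichlet).
random_stochastic_matrix <- function(L) {
  E <- matrix(rgamma(L * L, 1), L, L)
  E / rowSums(E)
}

random_simplex <- function(n) {
  p <- rgamma(n, 1)
  p / sum(p)
}

random_test_params <- function(structure) {
  L <- attr(structure, "n_levels")
  Q <- ncol(structure)
  polim_params(
    replicate(Q, random_stochastic_matrix(L), simplify = FALSE),
    random_simplex(nrow(structure)),
    structure
  )
}

# The two tabulated examples used across the monotonicity tests
# (levels a, b, c, d coded 0..3).
delta1_table <- function() {
  level_metric(matrix(
    c(
      0, 1, 3, 5,
      1, 0, 2, 3,
      3, 2, 0, 1,
      5, 3, 1, 0
    ),
    4, byrow = TRUE
  ))
}

f1_table <- function() {
  matrix(
    c(
      20, 18, 10, 5,
      10, 40, 5, 8,
      7, 8, 15, 4,
      1, 2, 3, 4
    ),
    4, byrow = TRUE
  )
}

# Order-respecting metric on a chain: random positive gaps, then a concave
# power transform (a metric transform that preserves the order of
# distances).
random_order_respecting_metric <- function(L) {
  gaps <- runif(L - 1, 0.2, 2)
  pos <- c(0, cumsum(gaps))
  p <- runif(1, 0.3, 1)
  level_metric(abs(outer(pos, pos, "-"))^p)
}

# A function monotone for the given metric: strictly decreasing transform
# of the distances, with row-specific scales.
monotone_function_for <- function(metric) {
  d <- as.matrix(metric)
  L <- nrow(d)
  a <- runif(L, 0.5, 2)
  exp(-d * rep(a, L)) * rep(runif(L, 0.5, 2), L)
}

expect_rowstochastic <- function(E, tol = 1e-10) {
  expect_true(all(E >= 0))
  expect_lt(max(abs(rowSums(E) - 1)), tol)
}
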