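# Constrained reparameterization of an error matrix through overrate and
# underrate decay rates. For a row with true level i, moving one level
# further from the diagonal multiplies the probability by a rate in (0, 1):
#   eps(i, k) = omega_ik * eps(i, k - 1)   for k > i   ("overrate" decay)
#   eps(i, k) = upsilon_ik * eps(i, k + 1) for k < i   ("underrate" decay)
# With all rates in (0, 1), each row is half-monotone by construction; the
# diagonal is determined by the rates through the row-sum constraint.

#' Overrate/underrate decay rates of one item
#'
#' Container for the rate parameterization of an error matrix. `omega[i, k]`
#' (0-based `i`, `k`, with `k > i`) is the ratio
#' `eps(i, k) / eps(i, k - 1)`; `upsilon[i, k]` (with `k < i`) is
#' `eps(i, k) / eps(i, k + 1)`. Cells outside those triangles are ignored
#' (may be `NA`). Every row of a chain with `n + 1` levels carries `n` free
#' rates, giving the `|L| (|L| - 1)` rates per item that replace the
#' inequality-constrained probabilities.
#'
#' @param omega,upsilon square matrices of rates (see above); entries indexed
#'   `[i + 1, k + 1]` for level codes `i`, `k`.
#' @param n_levels number of levels; defaults to `nrow(omega)`.
#' @param item optional item identifier.
#' @param strict if `TRUE` (default), rates must lie strictly in (0, 1);
#'   otherwise they are stored as-is and the `valid` attribute records
#'   whether they all do.
#' @return An object of class `rate_parameters`.
#' @export
rate_parameters <- function(omega, upsilon, n_levels = NULL, item = NULL,
                            strict = TRUE) {
  omega <- as.matrix(omega)
  upsilon <- as.matrix(upsilon)
  if (is.null(n_levels)) n_levels <- nrow(omega)
  L <- as.integer(n_levels)
  stopifnot(nrow(omega) == L, ncol(omega) == L,
            nrow(upsilon) == L, ncol(upsilon) == L)
  up <- row(omega) < col(omega)      # k > i: omega cells
  lo <- row(upsilon) > col(upsilon)  # k < i: upsilon cells
  omega[!up] <- NA_real_
  upsilon[!lo] <- NA_real_
  vals <- c(omega[up], upsilon[lo])
  ok <- all(!is.na(vals)) && all(vals > 0 & vals < 1)
  if (strict && !ok) {
    stop_input("all rates must lie strictly in (0, 1)")
  }
  structure(
    list(omega = omega, upsilon = upsilon, n_levels = L, item = item),
    valid = ok, class = "rate_parameters"
  )
}

#' @export
print.rate_parameters <- function(x, ...) {
  cat("Rate parameters (", x$n_levels, " levels",
      if (!is.null(x$item)) paste0(", item ", x$item), "): ",
      if (attr(x, "valid")) "all in (0,1)" else "OUT OF (0,1)", "\n",
      sep = "")
  cat("omega (overrate decay):\n"); print(round(x$omega, 6))
  cat("upsilon (underrate decay):\n"); print(round(x$upsilon, 6))
  invisible(x)
}

#' One error-matrix row from its decay rates
#'
#' `upsilon` holds the `i` underrate rates for the levels below the true
#' level `i` (ordered by level code `0..i-1`), `omega` the `n - i` overrate
#' rates above (level codes `i+1..n`). The diagonal entry is fixed by the
#' row-sum constraint; the returned row sums to 1 up to float rounding.
#'
#' @param upsilon,omega numeric vectors of rates in (0, 1); their lengths
#'   determine the true level and the number of levels.
#' @return Numeric probability row of length `length(upsilon) +
#'   length(omega) + 1`.
#' @examples
#' epsilon_row_from_rates(upsilon = c(.2, .1), omega = c(.3, .5)) * 157
#' @export
epsilon_row_from_rates <- function(upsilon, omega) {
  i <- length(upsilon)
  n <- i + length(omega)
  # below: prod of upsilon from level j up to i-1; above: prod of omega
  below <- if (i > 0) rev(cumprod(rev(upsilon))) else numeric(0)
  above <- if (n > i) cumprod(omega) else numeric(0)
  diag_val <- 1 / (1 + sum(below) + sum(above))
  c(below * diag_val, diag_val, above * diag_val)
}

#' Convert between rate parameters and error matrices
#'
#' `rates_to_epsilon()` builds the row-stochastic error matrix implied by a
#' set of decay rates: each row's diagonal is fixed by the row-sum
#' constraint and the off-diagonal entries decay multiplicatively away from
#' it, so every row is half-monotone under any order-respecting metric.
#' `epsilon_to_rates()` inverts the map by the exact ratio formulas; the
#' recovered rates lie in (0, 1) precisely when the rows are unimodal about
#' the diagonal, and the `valid` attribute of the result records whether
#' they do.
#'
#' @param rates a [rate_parameters] object.
#' @return For `rates_to_epsilon()`, a square row-stochastic matrix; for
#'   `epsilon_to_rates()`, a [rate_parameters] object (`strict = FALSE`).
#' @examples
#' om <- matrix(NA_real_, 3, 3)
#' up <- matrix(NA_real_, 3, 3)
#' om[upper.tri(om)] <- .4
#' up[lower.tri(up)] <- .3
#' E <- rates_to_epsilon(rate_parameters(om, up))
#' rowSums(E)
#' @export
rates_to_epsilon <- function(rates) {
  stopifnot(inherits(rates, "rate_parameters"))
  if (!attr(rates, "valid")) {
    stop_input("rates must lie strictly in (0, 1) to define an error matrix")
  }
  L <- rates$n_levels
  E <- matrix(0, L, L)
  for (i in seq_len(L)) {
    up <- if (i > 1) rates$upsilon[i, seq_len(i - 1L)] else numeric(0)
    om <- if (i < L) rates$omega[i, seq.int(i + 1L, L)] else numeric(0)
    E[i, ] <- epsilon_row_from_rates(up, om)
  }
  E
}

#' @rdname rates_to_epsilon
#' @param E square error matrix with strictly positive entries.
#' @param item optional item identifier carried through.
#' @export
epsilon_to_rates <- function(E, item = NULL) {
  E <- as.matrix(E)
  if (any(E <= 0)) stop_input("error matrix entries must be positive")
  L <- nrow(E)
  omega <- matrix(NA_real_, L, L)
  upsilon <- matrix(NA_real_, L, L)
  for (i in seq_len(L)) {
    if (i < L) {
      ks <- seq.int(i + 1L, L)
      omega[i, ks] <- E[i, ks] / E[i, ks - 1L]
    }
    if (i > 1) {
      ks <- seq_len(i - 1L)
      upsilon[i, ks] <- E[i, ks] / E[i, ks + 1L]
    }
  }
  rate_parameters(omega, upsilon, n_levels = L, item = item, strict = FALSE)
}
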