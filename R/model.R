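# The PoLIM probability model: conditional and marginal pattern
# probabilities, likelihood, parameter counting and response simulation.

#' PoLIM parameter set
#'
#' Bundles one row-stochastic error matrix per item with a probability
#' distribution over the states of a structure. Rows of every error matrix
#' must sum to 1 (tolerance 1e-10), as must the state probabilities.
#'
#' @param epsilon list of square error matrices, one per item, each of size
#'   `n_levels x n_levels`; entry `[i + 1, j + 1]` is the probability of
#'   observing level `j` when the latent level is `i`.
#' @param pi numeric vector of state probabilities, one per state of
#'   `structure`.
#' @param structure a [polim_structure].
#' @return An object of class `polim_params`.
#' @examples
#' ks <- polim_structure(rbind(c(0, 0), c(1, 1)), n_levels = 2)
#' E <- matrix(c(.9, .1, .2, .8), 2, byrow = TRUE)
#' polim_params(list(E, E), c(.5, .5), ks)
#' @export
polim_params <- function(epsilon, pi, structure) {
  stopifnot(inherits(structure, "polim_structure"))
  L <- n_levels_of(structure)
  Q <- ncol(structure)
  if (length(epsilon) != Q) {
    stop_input("need one error matrix per item (", Q, ")")
  }
  epsilon <- lapply(epsilon, function(E) {
    E <- as.matrix(E)
    if (nrow(E) != L || ncol(E) != L) {
      stop_input("error matrices must be ", L, " x ", L)
    }
    if (any(E < 0) || any(E > 1)) {
      stop_input("error-matrix entries must lie in [0, 1]")
    }
    if (any(abs(rowSums(E) - 1) > 1e-10)) {
      stop_input("error-matrix rows must sum to 1")
    }
    unname(E)
  })
  names(epsilon) <- items_of(structure)
  pi <- as.numeric(pi)
  if (length(pi) != nrow(structure)) {
    stop_input("need one state probability per state")
  }
  if (any(pi < 0) || abs(sum(pi) - 1) > 1e-10) {
    stop_input("state probabilities must be nonnegative and sum to 1")
  }
  out <- list(epsilon = epsilon, pi = pi, structure = structure)
  class(out) <- "polim_params"
  out
}

#' @export
print.polim_params <- function(x, ...) {
  st <- x$structure
  cat(
    "PoLIM parameters: ", ncol(st), " items, ", n_levels_of(st),
    " levels, ", nrow(st), " states (",
    count_free_parameters(st), " free parameters)\n",
    sep = ""
  )
  invisible(x)
}

#' Number of free parameters of a PoLIM
#'
#' `|Q| |L| (|L| - 1) + |K| - 1`: each of the `|Q| |L|` error-matrix rows
#' carries `|L| - 1` free probabilities, and the state distribution carries
#' `|K| - 1`. With two levels this reduces to the dichotomous model's
#' `2 |Q| + |K| - 1` careless-error/lucky-guess/state count.
#'
#' @param structure a [polim_structure].
#' @return Integer count.
#' @export
count_free_parameters <- function(structure) {
  L <- n_levels_of(structure)
  ncol(structure) * L * (L - 1L) + nrow(structure) - 1L
}

# Log conditional probability matrix: states (rows) x patterns (columns),
# entry log P(R | K) accumulated in the log domain item by item.
cond_log_matrix <- function(states, patterns, epsilon) {
  S <- nrow(states)
  P <- nrow(patterns)
  out <- matrix(0, S, P)
  for (q in seq_len(ncol(states))) {
    lE <- log(epsilon[[q]])
    out <- out + lE[states[, q] + 1L, patterns[, q] + 1L, drop = FALSE]
  }
  out
}

# Marginal probabilities P(R) for the pattern rows, via a log-sum-exp mix
# over the states.
marginal_prob_matrix <- function(patterns, params) {
  lc <- cond_log_matrix(params$structure, patterns, params$epsilon)
  lp <- log(params$pi)
  lj <- lc + lp # recycled down columns
  mx <- apply(lj, 2L, max)
  finite <- is.finite(mx)
  p <- numeric(ncol(lj))
  if (any(finite)) {
    sh <- exp(lj[, finite, drop = FALSE] -
      rep(mx[finite], each = nrow(lj)))
    p[finite] <- colSums(sh) * exp(mx[finite])
  }
  p
}

#' Conditional and marginal pattern probabilities
#'
#' `conditional_pattern_prob()` evaluates the local-independence product
#' `P(R | K) = prod_q eps_q(K(q), R(q))`; `marginal_pattern_prob()` mixes it
#' over the state distribution, `P(R) = sum_K P(R | K) pi_K`.
#'
#' @param R,K integer level vectors (a response pattern and a state).
#' @param params a [polim_params].
#' @return A probability.
#' @examples
#' ks <- polim_structure(rbind(c(0, 0), c(1, 1)), n_levels = 2)
#' E <- matrix(c(.9, .1, .2, .8), 2, byrow = TRUE)
#' p <- polim_params(list(E, E), c(.5, .5), ks)
#' conditional_pattern_prob(c(0, 1), c(1, 1), p)
#' marginal_pattern_prob(c(0, 1), p)
#' @export
conditional_pattern_prob <- function(R, K, params) {
  Q <- ncol(params$structure)
  if (length(R) != Q || length(K) != Q) {
    stop_input("pattern and state must have one level per item (", Q, ")")
  }
  exp(cond_log_matrix(
    matrix(as.integer(K), 1L), matrix(as.integer(R), 1L),
    params$epsilon
  )[1L, 1L])
}

#' @rdname conditional_pattern_prob
#' @export
marginal_pattern_prob <- function(R, params) {
  R <- if (is.matrix(R)) R else matrix(as.integer(R), 1L)
  p <- marginal_prob_matrix(R, params)
  if (nrow(R) == 1L) p[1L] else p
}

#' Multinomial log-likelihood of response data under a PoLIM
#'
#' `sum_R n_R log P(R)` over the distinct observed patterns.
#'
#' @param data a [polim_data].
#' @param params a [polim_params].
#' @return The log-likelihood value.
#' @export
log_likelihood <- function(data, params) {
  p <- marginal_prob_matrix(data$patterns, params)
  if (any(p <= 0)) {
    bad <- which(p <= 0)[1L]
    stop_input(
      "pattern ", state_keys(data$patterns[bad, , drop = FALSE],
        data$n_levels
      ),
      " has zero marginal probability"
    )
  }
  sum(data$freq * log(p))
}

#' Simulate response data from a PoLIM
#'
#' Each respondent draws a latent state from the state distribution, then
#' independently per item draws an observed level from the row of the
#' item's error matrix indexed by the state's level.
#'
#' @param params a [polim_params].
#' @param n number of respondents.
#' @param seed integer seed; the draw is reproducible given the seed.
#' @return A list with elements `data` (a [polim_data] of the simulated
#'   responses), `states` (the latent state matrix, one row per respondent)
#'   and `state_index` (row indices into the structure).
#' @examples
#' ks <- polim_structure(rbind(c(0, 0), c(1, 1)), n_levels = 2)
#' E <- matrix(c(.9, .1, .2, .8), 2, byrow = TRUE)
#' p <- polim_params(list(E, E), c(.5, .5), ks)
#' simulate_responses(p, 5, seed = 1)$data
#' @export
simulate_responses <- function(params, n, seed = NULL) {
  st <- params$structure
  L <- n_levels_of(st)
  Q <- ncol(st)
  with_seed(seed, {
    idx <- sample.int(nrow(st), n, replace = TRUE, prob = params$pi)
    latent <- st[idx, , drop = FALSE]
    resp <- matrix(0L, n, Q)
    for (q in seq_len(Q)) {
      E <- params$epsilon[[q]]
      lv <- latent[, q]
      for (i in seq_len(L) - 1L) {
        sel <- which(lv == i)
        if (length(sel)) {
          resp[sel, q] <- sample.int(L, length(sel),
            replace = TRUE,
            prob = E[i + 1L, ]
          ) - 1L
        }
      }
    }
    colnames(resp) <- items_of(st)
    list(
      data = polim_data(resp, n_levels = L, items = items_of(st)),
      states = latent,
      state_index = idx
    )
  })
}
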