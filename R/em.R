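# Maximum-likelihood estimation of the PoLIM by EM, unconstrained and with
# the half-monotonicity constraint through the rate reparameterization.

# Level-indicator matrices used by the M-step:
#   Sind[[q]] is L x S with entry (i+1, s) = 1 iff state s has level i on q;
#   Rind[[q]] is P x L with entry (p, j+1) = 1 iff pattern p has level j.
level_indicators <- function(mat, n_levels, transpose = FALSE) {
  lapply(seq_len(ncol(mat)), function(q) {
    M <- outer(seq_len(n_levels) - 1L, mat[, q], "==") * 1
    if (transpose) t(M) else M
  })
}

# Posterior weights (states x patterns, columns sum to 1) and the loglik,
# from precomputed log conditional probabilities.
estep <- function(lc, pi, freq) {
  lj <- lc + log(pi)
  mx <- apply(lj, 2L, max)
  w <- exp(lj - rep(mx, each = nrow(lj)))
  cs <- colSums(w)
  list(
    post = w / rep(cs, each = nrow(w)),
    loglik = sum(freq * (log(cs) + mx))
  )
}

# Complete-data expected counts: per item the L x L matrix with entry
# (i+1, j+1) = sum_R n_R sum_{K : K(q)=i, R(q)=j} w(K | R), plus the state
# totals. `post` columns must sum to 1.
expected_counts <- function(post, freq, Sind, Rind) {
  Wn <- post * rep(freq, each = nrow(post))
  counts <- lapply(seq_along(Sind), function(q) {
    (Sind[[q]] %*% Wn) %*% Rind[[q]]
  })
  list(counts = counts, state_mass = rowSums(Wn), N = sum(freq))
}

# Row-normalize expected counts into error matrices; zero-mass rows fall
# back to the uniform row and are flagged.
normalize_counts <- function(counts, floor) {
  flagged <- list()
  eps <- lapply(seq_along(counts), function(q) {
    Nq <- counts[[q]]
    denom <- rowSums(Nq)
    E <- Nq
    zero <- denom <= 0
    if (any(zero)) {
      E[zero, ] <- 1 / ncol(Nq)
      denom[zero] <- 1
      flagged[[length(flagged) + 1L]] <<- c(q, which(zero) - 1L)
    }
    E <- E / denom
    floor_rows(E, floor)
  })
  attr(eps, "flagged_rows") <- flagged
  eps
}

# Keep probabilities inside the open interval: floor then renormalize.
floor_rows <- function(E, floor) {
  E <- pmax(E, floor)
  E / rowSums(E)
}

floor_simplex <- function(p, floor) {
  p <- pmax(p, floor)
  p / sum(p)
}

default_epsilon <- function(Q, L, jitter = 1e-3) {
  # the flat 1/|L| start is a label-symmetric saddle of the EM map; a small
  # diagonal nudge anchors the truthful labeling without moving the start
  # appreciably
  E <- matrix(1 / L, L, L) + jitter * diag(L)
  E <- E / rowSums(E)
  rep(list(E), Q)
}

random_params <- function(structure, seed = NULL) {
  L <- n_levels_of(structure)
  Q <- ncol(structure)
  with_seed(seed, {
    eps <- lapply(seq_len(Q), function(q) {
      E <- matrix(rgamma(L * L, 1), L, L)
      E / rowSums(E)
    })
    pi <- rgamma(nrow(structure), 1)
    polim_params(eps, pi / sum(pi), structure)
  })
}

#' Posterior distribution over states given observed patterns
#'
#' Bayes rule per distinct pattern: `P(K | R)` proportional to
#' `P(R | K) pi_K`.
#'
#' @param data a [polim_data].
#' @param params a [polim_params].
#' @return Matrix with one row per distinct pattern and one column per
#'   state; rows sum to 1.
#' @export
posterior_states <- function(data, params) {
  lc <- cond_log_matrix(params$structure, data$patterns, params$epsilon)
  es <- estep(lc, params$pi, data$freq)
  if (!all(is.finite(es$loglik))) {
    stop_input("a pattern has zero marginal probability under these parameters")
  }
  t(es$post)
}

new_fit_result <- function(params, rates = NULL, trace, converged, seed,
                           settings) {
  structure(
    list(
      params = params, rates = rates, loglik = trace[length(trace)],
      loglik_trace = trace, iterations = length(trace) - 1L,
      converged = converged, seed = seed, settings = settings
    ),
    class = "polim_fit_result"
  )
}

#' Fit a PoLIM by (unconstrained) maximum likelihood via EM
#'
#' Alternates the posterior computation with the closed-form complete-data
#' maximizer: `pi_K` becomes the mean posterior mass of `K`, and
#' `eps_q(i, j)` the expected count of (latent level i, observed level j)
#' pairs normalized within the row. The log-likelihood never decreases.
#' Estimated probabilities are kept inside the open interval by a floor
#' (default 1e-12) with renormalization.
#'
#' The default initialization is the flat start (all error entries `1/|L|`,
#' uniform states) with a tiny diagonal nudge on the error matrices; the
#' exactly flat start is a label-symmetric fixed point of the EM map.
#' `init = "random"` draws a seeded random start; a [polim_params] object is
#' used as-is.
#'
#' @param data a [polim_data].
#' @param structure a [polim_structure].
#' @param init `"default"`, `"random"`, or a [polim_params] start.
#' @param tol convergence tolerance on the absolute log-likelihood change.
#' @param max_iter iteration cap.
#' @param seed seed for the random start (unused otherwise).
#' @param floor lower bound kept on every estimated probability.
#' @return A `polim_fit_result`: list with `params`, `loglik`,
#'   `loglik_trace`, `iterations`, `converged`, `seed`, `settings`.
#' @examples
#' ks <- polim_structure(rbind(c(0, 0), c(1, 1)), n_levels = 2)
#' E <- matrix(c(.95, .05, .1, .9), 2, byrow = TRUE)
#' truth <- polim_params(list(E, E), c(.4, .6), ks)
#' sim <- simulate_responses(truth, 500, seed = 7)
#' em_fit(sim$data, ks)$params$pi
#' @export
em_fit <- function(data, structure, init = "default", tol = 1e-6,
                   max_iter = 2000L, seed = NULL, floor = 1e-12) {
  check_conformance(data, structure)
  L <- n_levels_of(structure)
  Q <- ncol(structure)
  S <- nrow(structure)
  params <- resolve_init(init, structure, seed)
  eps <- lapply(params$epsilon, floor_rows, floor = floor)
  pi <- floor_simplex(params$pi, floor)
  Sind <- level_indicators(structure, L)
  Rind <- level_indicators(data$patterns, L, transpose = TRUE)
  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    lc <- cond_log_matrix(structure, data$patterns, eps)
    es <- estep(lc, pi, data$freq)
    trace <- c(trace, es$loglik)
    if (it > 1L && abs(trace[it] - trace[it - 1L]) < tol) {
      converged <- TRUE
      break
    }
    ec <- expected_counts(es$post, data$freq, Sind, Rind)
    pi <- floor_simplex(ec$state_mass / ec$N, floor)
    eps <- normalize_counts(ec$counts, floor)
  }
  if (!converged) {
    # record the likelihood of the final M-step update
    lc <- cond_log_matrix(structure, data$patterns, eps)
    trace <- c(trace, estep(lc, pi, data$freq)$loglik)
  }
  new_fit_result(
    params = polim_params(eps, pi, structure),
    trace = trace, converged = converged, seed = seed,
    settings = list(
      method = "em", init = if (is.character(init)) init else "supplied",
      tol = tol, max_iter = max_iter, floor = floor
    )
  )
}

resolve_init <- function(init, structure, seed) {
  if (inherits(init, "polim_params")) return(init)
  L <- n_levels_of(structure)
  Q <- ncol(structure)
  S <- nrow(structure)
  if (identical(init, "default")) {
    polim_params(default_epsilon(Q, L), rep(1 / S, S), structure)
  } else if (identical(init, "random")) {
    random_params(structure, seed)
  } else {
    stop_input("init must be \"default\", \"random\" or a polim_params object")
  }
}

check_conformance <- function(data, structure) {
  if (ncol(data$patterns) != ncol(structure)) {
    stop_input("data and structure have different numbers of items")
  }
  if (data$n_levels != n_levels_of(structure)) {
    stop_input("data and structure have different numbers of levels")
  }
}

# -- constrained EM ----------------------------------------------------------

# Expected complete-data log-likelihood of one error-matrix row as a
# function of its logit-scale rates (upsilons then omegas).
row_rate_objective <- function(theta, counts, i, L) {
  r <- plogis(theta)
  up <- if (i > 0L) r[seq_len(i)] else numeric(0)
  om <- if (i < L - 1L) r[seq.int(i + 1L, L - 1L)] else numeric(0)
  row <- epsilon_row_from_rates(up, om)
  -sum(counts * log(row))
}

# Maximize the row objective starting from the current rates; generalized EM
# (only improving steps are accepted).
update_row_rates <- function(counts, up, om, L) {
  i <- length(up)
  theta0 <- qlogis(c(up, om))
  f0 <- row_rate_objective(theta0, counts, i, L)
  opt <- tryCatch(
    optim(theta0, row_rate_objective,
      counts = counts, i = i, L = L,
      method = "BFGS", control = list(maxit = 50)
    ),
    error = function(e) NULL
  )
  if (is.null(opt) || !is.finite(opt$value) || opt$value >= f0) {
    list(up = up, om = om)
  } else {
    r <- plogis(opt$par)
    list(
      up = if (i > 0L) r[seq_len(i)] else numeric(0),
      om = if (i < L - 1L) r[seq.int(i + 1L, L - 1L)] else numeric(0)
    )
  }
}

default_rates <- function(Q, L, value = 0.5) {
  om <- matrix(NA_real_, L, L)
  up <- matrix(NA_real_, L, L)
  om[row(om) < col(om)] <- value
  up[row(up) > col(up)] <- value
  rep(list(rate_parameters(om, up, n_levels = L)), Q)
}

rates_list_to_epsilon <- function(rates) lapply(rates, rates_to_epsilon)

#' Fit a PoLIM with the half-monotonicity constraint via EM
#'
#' The error matrices are parameterized by overrate/underrate decay rates in
#' (0, 1) ([rates_to_epsilon()]), so every iterate is half-monotone by
#' construction. The M-step for each item row maximizes the expected
#' complete-data log-likelihood numerically on the logit scale of the rates
#' (BFGS, warm-started at the previous iterate); only improving steps are
#' accepted, giving a generalized EM whose observed log-likelihood never
#' decreases. The state distribution update is the usual closed form.
#'
#' @inheritParams em_fit
#' @param init_rates `"default"` (all rates 0.5), or a list of
#'   [rate_parameters], one per item.
#' @return A `polim_fit_result`; the `rates` element holds the fitted
#'   per-item rates.
#' @export
em_fit_constrained <- function(data, structure, init_rates = "default",
                               tol = 1e-6, max_iter = 2000L, seed = NULL,
                               floor = 1e-12) {
  check_conformance(data, structure)
  L <- n_levels_of(structure)
  Q <- ncol(structure)
  S <- nrow(structure)
  rates <- if (identical(init_rates, "default")) {
    default_rates(Q, L)
  } else {
    stopifnot(length(init_rates) == Q)
    init_rates
  }
  pi <- rep(1 / S, S)
  Sind <- level_indicators(structure, L)
  Rind <- level_indicators(data$patterns, L, transpose = TRUE)
  eps <- rates_list_to_epsilon(rates)
  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    lc <- cond_log_matrix(structure, data$patterns, eps)
    es <- estep(lc, pi, data$freq)
    trace <- c(trace, es$loglik)
    if (it > 1L && abs(trace[it] - trace[it - 1L]) < tol) {
      converged <- TRUE
      break
    }
    ec <- expected_counts(es$post, data$freq, Sind, Rind)
    pi <- floor_simplex(ec$state_mass / ec$N, floor)
    for (q in seq_len(Q)) {
      rq <- rates[[q]]
      for (i in seq_len(L) - 1L) {
        up <- if (i > 0L) rq$upsilon[i + 1L, seq_len(i)] else numeric(0)
        om <- if (i < L - 1L) {
          rq$omega[i + 1L, seq.int(i + 2L, L)]
        } else {
          numeric(0)
        }
        new <- update_row_rates(ec$counts[[q]][i + 1L, ], up, om, L)
        if (i > 0L) rq$upsilon[i + 1L, seq_len(i)] <- new$up
        if (i < L - 1L) rq$omega[i + 1L, seq.int(i + 2L, L)] <- new$om
      }
      rates[[q]] <- rq
    }
    eps <- rates_list_to_epsilon(rates)
  }
  if (!converged) {
    lc <- cond_log_matrix(structure, data$patterns, eps)
    trace <- c(trace, estep(lc, pi, data$freq)$loglik)
  }
  new_fit_result(
    params = polim_params(eps, pi, structure),
    rates = rates, trace = trace, converged = converged, seed = seed,
    settings = list(
      method = "em_constrained", tol = tol, max_iter = max_iter,
      floor = floor
    )
  )
}

#' Empirical identifiability check by multistart EM
#'
#' Fits the model repeatedly from random starting points and, among the
#' fits whose log-likelihood lies within `window` of the best one, reports
#' the range of log-likelihoods and the largest standard deviation observed
#' for any single parameter. A maximum below 1e-3 is the usual working
#' criterion for treating the parameters as (empirically) identifiable.
#'
#' @param data a [polim_data].
#' @param structure a [polim_structure].
#' @param n_restarts number of random starts (at least 2).
#' @param seed master seed; start `r` uses a derived seed.
#' @param window log-likelihood window around the best fit.
#' @param constrained fit the half-monotone model instead.
#' @param ... passed to [em_fit()] / [em_fit_constrained()].
#' @return List with `loglik_range` (over all fits), `loglik_best`,
#'   `max_param_sd` (within the window), `n_in_window`, `logliks`.
#' @export
identifiability_check <- function(data, structure, n_restarts, seed,
                                  window = 1e-3, constrained = FALSE, ...) {
  if (n_restarts < 2L) stop_input("need at least 2 restarts")
  fits <- lapply(seq_len(n_restarts), function(r) {
    s <- derive_seed(seed, r)
    if (constrained) {
      # random rate starts: uniform in (0.05, 0.95)
      L <- n_levels_of(structure)
      Q <- ncol(structure)
      rates <- with_seed(s, lapply(seq_len(Q), function(q) {
        om <- matrix(NA_real_, L, L)
        up <- matrix(NA_real_, L, L)
        om[row(om) < col(om)] <- runif(sum(row(om) < col(om)), .05, .95)
        up[row(up) > col(up)] <- runif(sum(row(up) > col(up)), .05, .95)
        rate_parameters(om, up, n_levels = L)
      }))
      em_fit_constrained(data, structure, init_rates = rates, seed = s, ...)
    } else {
      em_fit(data, structure, init = "random", seed = s, ...)
    }
  })
  lls <- vapply(fits, function(f) f$loglik, numeric(1))
  best <- max(lls)
  inw <- which(lls >= best - window)
  par_mat <- vapply(fits[inw], function(f) {
    c(unlist(f$params$epsilon), f$params$pi)
  }, numeric(length(unlist(fits[[1]]$params$epsilon)) +
    length(fits[[1]]$params$pi)))
  sds <- if (length(inw) > 1L) apply(par_mat, 1L, sd) else rep(0, nrow(par_mat))
  list(
    loglik_range = diff(range(lls)),
    loglik_best = best,
    max_param_sd = max(sds),
    n_in_window = length(inw),
    logliks = lls
  )
}
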