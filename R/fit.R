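# The modelling front end: polim() fits by any of the four estimation
# methods and returns a classed fit with the usual accessor methods.

#' Fit a polytomous local independence model
#'
#' Estimates the per-item error matrices and the state distribution of a
#' PoLIM on observed response data over a given structure, by one of four
#' methods: unconstrained maximum likelihood via EM, maximum likelihood
#' under the half-monotonicity constraint (rate reparameterization),
#' or closed-form minimum discrepancy under the Manhattan or Hamming
#' pattern-state distance.
#'
#' @param data a [polim_data], or an integer matrix of responses (one
#'   respondent per row).
#' @param structure a [polim_structure].
#' @param method estimation method.
#' @param tol,max_iter EM convergence controls (ignored by the MD methods).
#' @param init EM initialization (see [em_fit()]).
#' @param seed seed for any randomized initialization.
#' @param ... passed to the underlying fitting function.
#' @return An object of class `polim`: list with `params` (a
#'   [polim_params]), `result` (the full `polim_fit_result`), `method`,
#'   `data`, `structure`, `npar`, `loglik` and `call`. Supported methods:
#'   `print`, `summary`, `coef`, `logLik`, `predict`, `fitted`,
#'   `residuals`, `simulate`, `plot`.
#' @examples
#' ks <- polim_structure(rbind(c(0, 0), c(1, 2), c(2, 2)), n_levels = 3)
#' E <- matrix(c(.9, .05, .05, .05, .9, .05, .05, .05, .9), 3, byrow = TRUE)
#' truth <- polim_params(list(E, E), c(.3, .3, .4), ks)
#' sim <- simulate_responses(truth, 300, seed = 11)
#' fit <- polim(sim$data, ks, method = "em")
#' fit
#' coef(fit, "pi")
#' @export
polim <- function(data, structure,
                  method = c("em", "em_constrained", "md_manhattan",
                             "md_hamming"),
                  tol = 1e-6, max_iter = 2000L, init = "default",
                  seed = NULL, ...) {
  method <- match.arg(method)
  if (!inherits(data, "polim_data")) {
    data <- polim_data(data,
      n_levels = n_levels_of(structure),
      items = items_of(structure)
    )
  }
  result <- switch(method,
    em = em_fit(data, structure,
      init = init, tol = tol,
      max_iter = max_iter, seed = seed, ...
    ),
    em_constrained = em_fit_constrained(data, structure,
      tol = tol,
      max_iter = max_iter, seed = seed, ...
    ),
    md_manhattan = md_fit(data, structure,
      manhattan_metric(data$n_levels), ...
    ),
    md_hamming = md_fit(data, structure, hamming_metric(data$n_levels), ...)
  )
  out <- list(
    params = result$params, result = result, method = method,
    data = data, structure = structure,
    npar = count_free_parameters(structure),
    loglik = log_likelihood(data, result$params),
    call = match.call()
  )
  class(out) <- "polim"
  out
}

#' @export
print.polim <- function(x, ...) {
  cat("Polytomous local independence model (", x$method, ")\n", sep = "")
  st <- x$structure
  cat(
    "  ", ncol(st), " items, ", n_levels_of(st), " levels, ",
    nrow(st), " states; N = ", format(x$data$N), "\n",
    sep = ""
  )
  cat(
    "  log-likelihood ", format(x$loglik, digits = 8), " on ", x$npar,
    " free parameters\n",
    sep = ""
  )
  if (x$method %in% c("em", "em_constrained")) {
    cat(
      "  EM: ", x$result$iterations, " iterations, ",
      if (x$result$converged) "converged" else "NOT converged", "\n",
      sep = ""
    )
  }
  invisible(x)
}

#' @export
summary.polim <- function(object, ...) {
  eps <- object$params$epsilon
  dm <- manhattan_metric(object$data$n_levels)
  diagnostics <- data.frame(
    item = items_of(object$structure),
    modality = vapply(eps, function(E) as.logical(check_modality(E)),
      logical(1)
    ),
    overall_error = vapply(
      eps, function(E) as.logical(check_overall_error(E)),
      logical(1)
    ),
    half_monotone = vapply(
      eps, function(E) as.logical(is_delta_half_monotone(E, dm)),
      logical(1)
    ),
    monotone = vapply(
      eps, function(E) as.logical(is_delta_monotone(E, dm)),
      logical(1)
    )
  )
  out <- list(
    fit = object, diagnostics = diagnostics,
    pi_summary = summary(object$params$pi)
  )
  class(out) <- "summary.polim"
  out
}

#' @export
print.summary.polim <- function(x, ...) {
  print(x$fit)
  cat("\nRow-monotonicity diagnostics of the estimated error matrices:\n")
  print(x$diagnostics, row.names = FALSE)
  cat("\nState probabilities:\n")
  print(x$pi_summary)
  invisible(x)
}

#' @export
coef.polim <- function(object, type = c("all", "epsilon", "pi"), ...) {
  type <- match.arg(type)
  switch(type,
    all = list(epsilon = object$params$epsilon, pi = object$params$pi),
    epsilon = object$params$epsilon,
    pi = setNames(
      object$params$pi,
      state_keys(object$structure, n_levels_of(object$structure))
    )
  )
}

#' @export
logLik.polim <- function(object, ...) {
  structure(object$loglik,
    df = object$npar, nobs = object$data$N,
    class = "logLik"
  )
}

#' @export
predict.polim <- function(object, newdata = NULL,
                          type = c("marginal", "posterior"), ...) {
  type <- match.arg(type)
  patterns <- if (is.null(newdata)) {
    object$data$patterns
  } else if (inherits(newdata, "polim_data")) {
    newdata$patterns
  } else {
    m <- as.matrix(newdata)
    storage.mode(m) <- "integer"
    m
  }
  if (type == "marginal") {
    marginal_prob_matrix(patterns, object$params)
  } else {
    posterior_states(
      polim_data(patterns,
        n_levels = object$data$n_levels,
        items = object$data$items
      ),
      object$params
    )
  }
}

#' @export
fitted.polim <- function(object, ...) {
  object$data$N * marginal_prob_matrix(object$data$patterns, object$params)
}

#' @export
residuals.polim <- function(object, ...) {
  # Pearson residuals of the distinct-pattern frequencies
  p <- marginal_prob_matrix(object$data$patterns, object$params)
  e <- object$data$N * p
  (object$data$freq - e) / sqrt(pmax(e * (1 - p), .Machine$double.eps))
}

#' @export
simulate.polim <- function(object, nsim = 1, seed = NULL, ...) {
  n <- object$data$N
  lapply(seq_len(nsim), function(s) {
    simulate_responses(object$params, n,
      seed = if (is.null(seed)) NULL else derive_seed(seed, s)
    )$data
  })
}

#' @export
plot.polim <- function(x, ...) {
  obs <- x$data$freq
  fit <- fitted(x)
  plot(fit, obs,
    xlab = "expected pattern frequency",
    ylab = "observed pattern frequency",
    main = paste0("PoLIM fit (", x$method, ")"), ...
  )
  abline(0, 1, lty = 2)
  invisible(x)
}
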