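# Parameter-recovery simulation study: scenario-based truth generation,
# the recovery experiment over replications, and bootstrap standard errors.

#' Configuration of a recovery scenario
#'
#' The study conditions: a random structure containing the bottom and top
#' states with a uniform state distribution; per item and level a diagonal
#' "true positive" probability drawn uniformly from `[m, 1)` with
#' `m > 1/2`; off-diagonal entries drawn uniformly and normalized to the
#' remaining row mass. In the monotone-truth scenario the same off-diagonal
#' values are reordered to decay away from the diagonal on each side, so
#' both scenarios share diagonals and per-row off-diagonal value multisets
#' given the same seed. The reference design uses 10 items, 4 levels, a
#' 1,000-state structure, `m` in \{.75, .85, .95\}, samples of 2,000 or
#' 5,000 respondents and 100 replications.
#'
#' @param num_items,num_levels,structure_size domain and structure sizes.
#' @param m lower bound of the diagonal probabilities, in (1/2, 1).
#' @param monotone_truth if `TRUE`, the true error matrices additionally
#'   respect half-monotonicity.
#' @param n_samples respondents per simulated data set.
#' @param n_replications number of simulated data sets.
#' @param seed master seed for the structure, the truth and the samples.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(num_items = 10, num_levels = 4,
                            structure_size = 1000, m = 0.95,
                            monotone_truth = FALSE, n_samples = 2000,
                            n_replications = 100, seed = 1) {
  if (m <= 0.5 || m >= 1) stop_input("m must lie in (0.5, 1)")
  structure(
    list(
      num_items = as.integer(num_items),
      num_levels = as.integer(num_levels),
      structure_size = as.integer(structure_size),
      m = m, monotone_truth = isTRUE(monotone_truth),
      n_samples = as.integer(n_samples),
      n_replications = as.integer(n_replications),
      seed = as.integer(seed)
    ),
    class = "scenario_config"
  )
}

# Position order used to impose monotone decay: off-diagonal cells of row i
# sorted by distance from the diagonal, lower side first on ties.
monotone_position_order <- function(i, L) {
  js <- setdiff(seq_len(L) - 1L, i)
  js[order(abs(js - i), js > i)]
}

#' Generate the true error matrices of a recovery scenario
#'
#' Diagonals are uniform on `[m, 1)`; off-diagonals are uniform draws
#' normalized to `1 - diag` (so every row satisfies the overall-error
#' condition). With `monotone_truth = TRUE` the same off-diagonal values are
#' reassigned in decreasing size to positions of increasing distance from
#' the diagonal, making every row half-monotone while preserving the
#' per-row value multiset of the non-monotone scenario under the same seed.
#'
#' @param config a [scenario_config].
#' @param seed seed; defaults to the config's seed.
#' @return List of error matrices, one per item.
#' @export
generate_true_epsilon <- function(config, seed = config$seed) {
  L <- config$num_levels
  with_seed(derive_seed(seed, 211L), {
    lapply(seq_len(config$num_items), function(q) {
      E <- matrix(0, L, L)
      for (i in seq_len(L) - 1L) {
        diag_val <- runif(1, config$m, 1)
        off <- runif(L - 1L)
        off <- off / sum(off) * (1 - diag_val)
        E[i + 1L, i + 1L] <- diag_val
        if (config$monotone_truth) {
          pos <- monotone_position_order(i, L)
          E[i + 1L, pos + 1L] <- sort(off, decreasing = TRUE)
        } else {
          E[i + 1L, setdiff(seq_len(L), i + 1L)] <- off
        }
      }
      E
    })
  })
}

recovery_methods <- c("em", "em_constrained", "md_hamming", "md_manhattan")

fit_by_method <- function(method, data, structure, em_control) {
  switch(method,
    em = em_fit(data, structure,
      tol = em_control$tol, max_iter = em_control$max_iter
    ),
    em_constrained = em_fit_constrained(data, structure,
      tol = em_control$tol, max_iter = em_control$max_iter
    ),
    md_hamming = md_fit(data, structure, hamming_metric(data$n_levels)),
    md_manhattan = md_fit(data, structure, manhattan_metric(data$n_levels)),
    stop_input("unknown method: ", method)
  )
}

#' Run the parameter-recovery experiment
#'
#' Builds the scenario's structure (held fixed, uniform state distribution)
#' and true error matrices, then for each replication simulates a sample
#' and fits it with each requested method. Reports, per method and
#' parameter class (state probabilities; error entries above the diagonal,
#' `i < j`; below, `i > j`), the mean bias and mean absolute bias of the
#' replication-averaged estimates, and the average and maximum standard
#' error (the standard deviation of each parameter's estimates across
#' replications). Per-replication seeds derive from the master seed, so the
#' experiment is reproducible and parallelizable by replication.
#'
#' @param config a [scenario_config].
#' @param methods subset of `"em"`, `"em_constrained"`, `"md_hamming"`,
#'   `"md_manhattan"`.
#' @param em_control list with `tol` and `max_iter` for the EM fits.
#' @return A `recovery_report`: list with `summary` (data frame), `truth`,
#'   per-method arrays of mean estimates and SEs, `failures`, and the
#'   config.
#' @export
run_recovery <- function(config, methods = recovery_methods,
                         em_control = list(tol = 1e-5, max_iter = 500L)) {
  methods <- match.arg(methods, recovery_methods, several.ok = TRUE)
  ks <- random_structure(
    config$num_items, config$num_levels,
    config$structure_size,
    seed = derive_seed(config$seed, 101L)
  )
  pi_true <- rep(1 / nrow(ks), nrow(ks))
  eps_true <- generate_true_epsilon(config)
  truth <- polim_params(eps_true, pi_true, ks)
  L <- config$num_levels
  Q <- config$num_items
  est_eps <- lapply(methods, function(m) {
    array(NA_real_, c(L, L, Q, config$n_replications))
  })
  names(est_eps) <- methods
  est_pi <- lapply(methods, function(m) {
    matrix(NA_real_, nrow(ks), config$n_replications)
  })
  names(est_pi) <- methods
  failures <- list()
  for (r in seq_len(config$n_replications)) {
    sim <- simulate_responses(truth, config$n_samples,
      seed = derive_seed(config$seed, 500L + r)
    )
    for (m in methods) {
      fit <- tryCatch(
        fit_by_method(m, sim$data, ks, em_control),
        error = function(e) e
      )
      if (inherits(fit, "error")) {
        failures[[length(failures) + 1L]] <- list(
          replication = r, method = m, message = conditionMessage(fit)
        )
        next
      }
      for (q in seq_len(Q)) est_eps[[m]][, , q, r] <- fit$params$epsilon[[q]]
      est_pi[[m]][, r] <- fit$params$pi
    }
  }
  summarize_recovery(methods, est_eps, est_pi, eps_true, pi_true, config,
    failures = failures
  )
}

summarize_recovery <- function(methods, est_eps, est_pi, eps_true, pi_true,
                               config, failures) {
  L <- config$num_levels
  off_lower <- which(row(diag(L)) > col(diag(L))) # i > j
  off_upper <- which(row(diag(L)) < col(diag(L))) # i < j
  rows <- NULL
  mean_eps <- list()
  se_eps <- list()
  mean_pi <- list()
  se_pi <- list()
  for (m in methods) {
    em <- apply(est_eps[[m]], 1:3, mean, na.rm = TRUE)
    es <- apply(est_eps[[m]], 1:3, sd, na.rm = TRUE)
    pm <- rowMeans(est_pi[[m]], na.rm = TRUE)
    ps <- apply(est_pi[[m]], 1L, sd, na.rm = TRUE)
    mean_eps[[m]] <- em
    se_eps[[m]] <- es
    mean_pi[[m]] <- pm
    se_pi[[m]] <- ps
    bias <- em - simplify2array(eps_true)
    cls <- list(
      pi = list(bias = pm - pi_true, se = ps),
      eps_upper = list(
        bias = as.vector(apply(bias, 3L, function(B) B[off_upper])),
        se = as.vector(apply(es, 3L, function(B) B[off_upper]))
      ),
      eps_lower = list(
        bias = as.vector(apply(bias, 3L, function(B) B[off_lower])),
        se = as.vector(apply(es, 3L, function(B) B[off_lower]))
      )
    )
    for (cn in names(cls)) {
      rows <- rbind(rows, data.frame(
        method = m, class = cn,
        mean_bias = mean(cls[[cn]]$bias),
        mean_abs_bias = mean(abs(cls[[cn]]$bias)),
        avg_se = mean(cls[[cn]]$se),
        max_se = max(cls[[cn]]$se)
      ))
    }
  }
  structure(
    list(
      summary = rows, truth = list(epsilon = eps_true, pi = pi_true),
      mean_epsilon = mean_eps, se_epsilon = se_eps,
      mean_pi = mean_pi, se_pi = se_pi,
      failures = failures, config = config
    ),
    class = "recovery_report"
  )
}

#' @export
print.recovery_report <- function(x, ...) {
  cfg <- x$config
  cat(
    "Parameter recovery: ", cfg$n_replications, " replications, N = ",
    cfg$n_samples, ", m = ", cfg$m, ", ",
    if (cfg$monotone_truth) "monotone" else "non-monotone", " truth\n",
    sep = ""
  )
  print(x$summary, digits = 4, row.names = FALSE)
  if (length(x$failures)) cat(length(x$failures), "fit failures\n")
  invisible(x)
}

#' Bootstrap standard errors of PoLIM estimates
#'
#' Nonparametric bootstrap over respondents: resample the sample with
#' replacement, refit, and report the standard deviation of every parameter
#' estimate across the refits.
#'
#' @param data a [polim_data] with integer frequencies.
#' @param structure a [polim_structure].
#' @param fit_settings list with `method` (one of the recovery methods) and
#'   optional `tol`, `max_iter`.
#' @param n_boot number of bootstrap resamples (at least 2).
#' @param seed master seed.
#' @return List with `epsilon_se` (list of per-item SE matrices) and
#'   `pi_se`.
#' @export
bootstrap_se <- function(data, structure,
                         fit_settings = list(method = "em"),
                         n_boot = 50L, seed = 1L) {
  if (n_boot < 2L) stop_input("need at least 2 bootstrap resamples")
  method <- fit_settings$method
  emc <- list(
    tol = fit_settings$tol %||% 1e-5,
    max_iter = fit_settings$max_iter %||% 500L
  )
  resp <- expand_respondents(data)
  N <- nrow(resp)
  L <- data$n_levels
  Q <- length(data$items)
  eps_arr <- array(NA_real_, c(L, L, Q, n_boot))
  pi_arr <- matrix(NA_real_, nrow(structure), n_boot)
  for (b in seq_len(n_boot)) {
    idx <- with_seed(derive_seed(seed, b), sample.int(N, N, replace = TRUE))
    db <- polim_data(resp[idx, , drop = FALSE],
      n_levels = L,
      items = data$items
    )
    fit <- fit_by_method(method, db, structure, emc)
    for (q in seq_len(Q)) eps_arr[, , q, b] <- fit$params$epsilon[[q]]
    pi_arr[, b] <- fit$params$pi
  }
  list(
    epsilon_se = lapply(seq_len(Q), function(q) {
      apply(eps_arr[, , q, , drop = FALSE], c(1, 2), sd)
    }),
    pi_se = apply(pi_arr, 1L, sd)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
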