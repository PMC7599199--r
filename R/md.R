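# Minimum-discrepancy estimation: each observed pattern is attributed,
# with uniform weight, to the states at minimum distance from it; the
# parameter estimates are then the closed-form complete-data maximizers
# under those weights.

#' Additive pattern-state distance
#'
#' The discrepancy between a response pattern and a state is the sum over
#' items of the level-metric distance between the observed and the latent
#' level. With the Manhattan metric this is the Manhattan discrepancy used
#' throughout structure extraction; with the Hamming metric it counts
#' disagreeing items (the symmetric-difference distance of the dichotomous
#' theory).
#'
#' @param R,K integer level vectors of equal length.
#' @param metric a [level_metric].
#' @return Nonnegative distance; 0 iff `R == K`.
#' @examples
#' pattern_state_distance(c(0, 3), c(1, 1), manhattan_metric(4))
#' @export
pattern_state_distance <- function(R, K, metric) {
  if (length(R) != length(K)) stop_input("pattern/state length mismatch")
  d <- as.matrix(metric)
  sum(d[cbind(R + 1L, K + 1L)])
}

# All pattern-state distances at once: states (rows) x patterns (cols).
distance_matrix <- function(states, patterns, metric) {
  d <- as.matrix(metric)
  S <- nrow(states)
  P <- nrow(patterns)
  out <- matrix(0, S, P)
  for (q in seq_len(ncol(states))) {
    out <- out + d[states[, q] + 1L, patterns[, q] + 1L, drop = FALSE]
  }
  out
}

#' States at minimum distance from a pattern
#'
#' Exhaustive scan of the structure; all tied states are retained.
#'
#' @param R integer response pattern.
#' @param structure a [polim_structure].
#' @param metric a [level_metric].
#' @return List with `states` (row indices into the structure) and
#'   `distance`.
#' @export
min_distance_states <- function(R, structure, metric) {
  d <- distance_matrix(structure, matrix(as.integer(R), 1L), metric)[, 1L]
  m <- min(d)
  list(states = which(d <= m + 1e-9), distance = m)
}

#' Fit a PoLIM by minimum discrepancy
#'
#' Non-iterative estimator: every observed pattern is assigned uniformly to
#' its minimum-distance states under the chosen level metric, and the
#' parameters are the complete-data maximizers under those assignment
#' weights — state probabilities proportional to assigned frequency mass,
#' error entries proportional to the expected (latent level, observed
#' level) counts. Error-matrix rows for latent levels that no
#' minimum-distance state attains carry no information; they fall back to
#' the uniform row and are flagged in the `flagged_rows` attribute of the
#' result's error list.
#'
#' @param data a [polim_data].
#' @param structure a [polim_structure].
#' @param metric a [level_metric], typically [manhattan_metric()] or
#'   [hamming_metric()].
#' @param floor lower bound kept on every estimated probability.
#' @return A `polim_fit_result` (with `iterations = 0`); the element
#'   `assignment` holds the states-by-patterns weight matrix.
#' @examples
#' ks <- polim_structure(rbind(c(0, 0), c(1, 1)), n_levels = 2)
#' d <- polim_data(rbind(c(0, 0), c(1, 1), c(1, 1)))
#' md_fit(d, ks, manhattan_metric(2))$params$pi
#' @export
md_fit <- function(data, structure, metric = manhattan_metric(data$n_levels),
                   floor = 1e-12) {
  check_conformance(data, structure)
  L <- n_levels_of(structure)
  D <- distance_matrix(structure, data$patterns, metric)
  mins <- apply(D, 2L, min)
  u <- (D <= rep(mins, each = nrow(D)) + 1e-9) * 1
  u <- u / rep(colSums(u), each = nrow(u))
  Sind <- level_indicators(structure, L)
  Rind <- level_indicators(data$patterns, L, transpose = TRUE)
  ec <- expected_counts(u, data$freq, Sind, Rind)
  pi <- floor_simplex(ec$state_mass / ec$N, floor)
  eps <- normalize_counts(ec$counts, floor)
  if (length(attr(eps, "flagged_rows"))) {
    warning("some error-matrix rows received no minimum-distance mass; ",
      "uniform fallback used",
      call. = FALSE
    )
  }
  res <- new_fit_result(
    params = polim_params(eps, pi, structure),
    trace = log_likelihood(data, polim_params(eps, pi, structure)),
    converged = TRUE, seed = NULL,
    settings = list(method = "md", floor = floor)
  )
  res$iterations <- 0L
  res$assignment <- u
  res$flagged_rows <- attr(eps, "flagged_rows")
  res
}
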