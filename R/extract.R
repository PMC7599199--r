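# Data-driven structure extraction: k-median clustering of ordinal response
# patterns under the Manhattan discrepancy, validated by the minimax
# criterion on a held-out set.

# Weighted lower median of integer level values: smallest value whose
# cumulative frequency reaches half the total.
weighted_lower_median <- function(values, freq) {
  o <- order(values)
  cs <- cumsum(freq[o])
  values[o][which(cs >= cs[length(cs)] / 2)[1L]]
}

#' Extract a structure by k-median clustering
#'
#' Alternates a pattern-classification step (assign every observed pattern
#' to the nearest centroid under the per-item Manhattan sum; ties go to the
#' lowest-index centroid) with a centroid-adjustment step (replace each
#' centroid by the frequency-weighted component-wise lower median of its
#' assigned patterns). Both steps weakly decrease the total within-cluster
#' Manhattan discrepancy, so the algorithm reaches a fixed point; empty
#' clusters are dropped. The distinct final centroids form the extracted
#' structure.
#'
#' @param data a [polim_data].
#' @param initial_centroids integer matrix of starting states, one per row.
#' @param max_iter iteration cap.
#' @return A [polim_structure] of the distinct final centroids, with
#'   attributes `iterations` and `objective` (trace of the within-cluster
#'   discrepancy).
#' @export
kmedian_extract <- function(data, initial_centroids, max_iter = 100L) {
  C <- as.matrix(initial_centroids)
  storage.mode(C) <- "integer"
  if (ncol(C) != ncol(data$patterns)) {
    stop_input("centroids and data have different numbers of items")
  }
  metric <- manhattan_metric(data$n_levels)
  pat <- data$patterns
  freq <- data$freq
  objective <- numeric(0)
  for (it in seq_len(max_iter)) {
    D <- distance_matrix(C, pat, metric) # centroids x patterns
    assign_idx <- max.col(-t(D), ties.method = "first")
    objective <- c(objective, sum(freq * D[cbind(assign_idx, seq_along(freq))]))
    newC <- C
    keep <- logical(nrow(C))
    for (k in seq_len(nrow(C))) {
      sel <- assign_idx == k
      if (!any(sel)) next
      keep[k] <- TRUE
      for (q in seq_len(ncol(C))) {
        newC[k, q] <- weighted_lower_median(pat[sel, q], freq[sel])
      }
    }
    newC <- newC[keep, , drop = FALSE]
    if (nrow(newC) == nrow(C) && all(newC == C)) break
    C <- newC
  }
  out <- polim_structure(unique(C),
    n_levels = data$n_levels,
    items = data$items
  )
  attr(out, "iterations") <- it
  attr(out, "objective") <- objective
  out
}

#' Asymmetric discrepancies between data and a structure
#'
#' `discrepancy_data_to_structure()` is the frequency-weighted mean, over
#' respondents, of the minimum Manhattan distance from their pattern to the
#' structure; it is 0 exactly when every observed pattern is a state.
#' `discrepancy_structure_to_data()` is the mean, over states, of the
#' minimum distance to a distinct observed pattern; it is 0 exactly when
#' every state was observed. The two are not symmetric.
#'
#' @param data a [polim_data].
#' @param structure a [polim_structure].
#' @param metric level metric; Manhattan by default.
#' @return Nonnegative mean minimum distance.
#' @export
discrepancy_data_to_structure <- function(data, structure,
                                          metric =
                                            manhattan_metric(data$n_levels)) {
  D <- distance_matrix(structure, data$patterns, metric)
  sum(data$freq * apply(D, 2L, min)) / data$N
}

#' @rdname discrepancy_data_to_structure
#' @export
discrepancy_structure_to_data <- function(structure, data,
                                          metric =
                                            manhattan_metric(data$n_levels)) {
  D <- distance_matrix(structure, data$patterns, metric)
  mean(apply(D, 1L, min))
}

#' Select a structure by the minimax discrepancy criterion
#'
#' For each candidate structure, both asymmetric discrepancies against the
#' validation data are computed; the selected structure minimizes the
#' larger of the two. Ties are broken by smaller structure size, then input
#' order.
#'
#' @param candidates list of [polim_structure] objects.
#' @param d2 validation [polim_data].
#' @return An `extraction_result`: list with `structures`, `discrepancies`
#'   (matrix with columns `data_to_structure`, `structure_to_data`, `max`),
#'   `selected` (index), `structure` (the winner) and `z` (the minimax
#'   value).
#' @export
minimax_select <- function(candidates, d2) {
  if (!length(candidates)) stop_input("no candidate structures")
  disc <- t(vapply(candidates, function(ks) {
    a <- discrepancy_data_to_structure(d2, ks)
    b <- discrepancy_structure_to_data(ks, d2)
    c(a, b, max(a, b))
  }, numeric(3)))
  colnames(disc) <- c("data_to_structure", "structure_to_data", "max")
  sizes <- vapply(candidates, nrow, integer(1))
  ord <- order(disc[, "max"], sizes, seq_along(candidates))
  sel <- ord[1L]
  structure(
    list(
      structures = candidates, discrepancies = disc, selected = sel,
      structure = candidates[[sel]], z = unname(disc[sel, "max"])
    ),
    class = "extraction_result"
  )
}

#' @export
print.extraction_result <- function(x, ...) {
  cat(
    "Structure extraction: ", length(x$structures), " candidates, ",
    "selected #", x$selected, " (", nrow(x$structure), " states), z = ",
    format(x$z, digits = 4), "\n",
    sep = ""
  )
  invisible(x)
}

#' Full extraction pipeline with random partitions and the minimax criterion
#'
#' Repeats, for each of `n_partitions` random splits of the respondents
#' into an extraction set (two thirds) and a validation set (one third) and
#' for each requested number of initial centroids: sample the initial
#' centroids without replacement from the distinct observed patterns of the
#' extraction set, run [kmedian_extract()], and score the result on the
#' validation set. The structure minimizing the larger of the two
#' discrepancies across the whole grid is selected.
#'
#' @param data a [polim_data] (integer frequencies).
#' @param n_partitions number of random splits.
#' @param centroid_sizes numbers of initial centroids to try.
#' @param seed master seed; every split and centroid draw derives from it.
#' @param max_iter k-median iteration cap.
#' @return An `extraction_result` with an extra `grid` data frame
#'   (partition, size, final size, discrepancies).
#' @export
extraction_pipeline <- function(data, n_partitions, centroid_sizes, seed,
                                max_iter = 100L) {
  resp <- expand_respondents(data)
  N <- nrow(resp)
  n2 <- max(1L, round(N / 3))
  candidates <- list()
  grid <- NULL
  d2_list <- list()
  for (p in seq_len(n_partitions)) {
    sp <- derive_seed(seed, p)
    idx2 <- with_seed(sp, sample.int(N, n2))
    d1 <- polim_data(resp[-idx2, , drop = FALSE],
      n_levels = data$n_levels, items = data$items
    )
    d2 <- polim_data(resp[idx2, , drop = FALSE],
      n_levels = data$n_levels, items = data$items
    )
    for (s in seq_along(centroid_sizes)) {
      size <- centroid_sizes[s]
      if (size > nrow(d1$patterns)) {
        stop_input(
          "centroid size ", size, " exceeds the ",
          nrow(d1$patterns), " distinct patterns of the extraction set"
        )
      }
      pick <- with_seed(
        derive_seed(sp, s),
        sample.int(nrow(d1$patterns), size)
      )
      ks <- kmedian_extract(d1, d1$patterns[pick, , drop = FALSE],
        max_iter = max_iter
      )
      candidates[[length(candidates) + 1L]] <- ks
      d2_list[[length(d2_list) + 1L]] <- d2
      grid <- rbind(grid, data.frame(
        partition = p, size_requested = size, size_final = nrow(ks)
      ))
    }
  }
  # each candidate is scored against the validation half of its own split
  disc <- t(vapply(seq_along(candidates), function(i) {
    a <- discrepancy_data_to_structure(d2_list[[i]], candidates[[i]])
    b <- discrepancy_structure_to_data(candidates[[i]], d2_list[[i]])
    c(a, b, max(a, b))
  }, numeric(3)))
  colnames(disc) <- c("data_to_structure", "structure_to_data", "max")
  sizes <- vapply(candidates, nrow, integer(1))
  sel <- order(disc[, "max"], sizes, seq_along(candidates))[1L]
  out <- structure(
    list(
      structures = candidates, discrepancies = disc, selected = sel,
      structure = candidates[[sel]], z = unname(disc[sel, "max"])
    ),
    class = "extraction_result"
  )
  out$grid <- cbind(grid, disc)
  out
}
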