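#' Polytomous knowledge structure
#'
#' A polytomous structure is a finite nonempty set of states over a common
#' item domain, each state assigning one of `n_levels` ordered response
#' levels (coded `0 ... n_levels - 1`) to every item.
#'
#' @param states integer matrix, one state per row, one column per item.
#' @param n_levels number of response levels (at least 2). Defaults to
#'   `max(states) + 1`.
#' @param items character vector of item identifiers; defaults to the column
#'   names of `states` or `q1, q2, ...`.
#' @return An object of class `polim_structure`: the (deduplicated) state
#'   matrix with attributes `n_levels` and `items`.
#' @examples
#' polim_structure(rbind(c(0, 0), c(1, 2), c(2, 2)), n_levels = 3)
#' @export
polim_structure <- function(states, n_levels = NULL, items = NULL) {
  states <- as.matrix(states)
  if (nrow(states) < 1L) stop_input("a structure needs at least one state")
  storage.mode(states) <- "integer"
  if (anyNA(states) || any(states < 0L)) {
    stop_input("state levels must be nonnegative integers")
  }
  if (is.null(n_levels)) n_levels <- max(states) + 1L
  n_levels <- as.integer(n_levels)
  if (n_levels < 2L) stop_input("need at least 2 levels")
  if (any(states >= n_levels)) {
    stop_input("state levels must lie in 0..", n_levels - 1L)
  }
  if (is.null(items)) items <- colnames(states)
  if (is.null(items)) items <- paste0("q", seq_len(ncol(states)))
  if (anyDuplicated(items)) stop_input("item identifiers must be distinct")
  states <- unique(states)
  dimnames(states) <- list(NULL, items)
  structure(states,
    n_levels = n_levels, items = items,
    class = c("polim_structure", "matrix", "array")
  )
}

#' @export
print.polim_structure <- function(x, ...) {
  cat(
    "Polytomous structure: ", nrow(x), " states, ", ncol(x), " items, ",
    attr(x, "n_levels"), " levels\n",
    sep = ""
  )
  k <- min(nrow(x), 6L)
  keys <- state_keys(x[seq_len(k), , drop = FALSE], attr(x, "n_levels"))
  cat("  ", paste(keys, collapse = " "), if (nrow(x) > k) " ..." else "",
    "\n",
    sep = ""
  )
  invisible(x)
}

n_levels_of <- function(x) attr(x, "n_levels")
items_of <- function(x) attr(x, "items")

#' Pointwise order between two polytomous states
#'
#' `K1` lies below `K2` in the pointwise order iff `K1(q) <= K2(q)` for every
#' item `q`. This partial order plays the role the subset order plays for
#' dichotomous knowledge states.
#'
#' @param k1,k2 integer vectors of equal length (level codes per item).
#' @return `TRUE` or `FALSE`.
#' @examples
#' pointwise_leq(c(0, 0), c(1, 2))
#' pointwise_leq(c(2, 0), c(1, 3))
#' @export
pointwise_leq <- function(k1, k2) {
  if (length(k1) != length(k2)) {
    stop_input("states live on different domains (lengths ", length(k1),
      " vs ", length(k2), ")")
  }
  all(k1 <= k2)
}

#' Random polytomous structure containing the bottom and top states
#'
#' Generates a structure of `size` distinct states over `num_items` items
#' with `num_levels` levels: the all-zero state, the all-maximum state, and
#' `size - 2` further states sampled uniformly without replacement from the
#' remaining points of the pattern space. Sampling is by rejection on a
#' seeded stream, so the full pattern space is never materialized.
#'
#' @param num_items,num_levels domain size and number of levels.
#' @param size number of states, between 2 and `num_levels^num_items`.
#' @param seed integer seed; the result is reproducible given the seed.
#' @return A [polim_structure].
#' @examples
#' random_structure(4, 3, 10, seed = 1)
#' @export
random_structure <- function(num_items, num_levels, size, seed) {
  num_items <- as.integer(num_items)
  num_levels <- as.integer(num_levels)
  size <- as.integer(size)
  total <- num_levels^as.double(num_items)
  if (size < 2L || size > total) {
    stop_input("size must be between 2 and num_levels^num_items = ", total)
  }
  bottom <- rep(0L, num_items)
  top <- rep(num_levels - 1L, num_items)
  want <- size - 2L
  picked <- with_seed(seed, {
    if (want == 0L) {
      matrix(integer(0), 0L, num_items)
    } else if (total <= 2^20 && want > 0.25 * (total - 2)) {
      # dense case: rejection would thrash, enumerate instead
      all_p <- enumerate_patterns(num_items, num_levels, cap = 2^20)
      keys <- state_keys(all_p, num_levels)
      keep <- !(keys %in% state_keys(rbind(bottom, top), num_levels))
      all_p[sample(which(keep), want), , drop = FALSE]
    } else {
      seen <- new.env(hash = TRUE, parent = emptyenv())
      assign(state_keys(rbind(bottom), num_levels), TRUE, envir = seen)
      assign(state_keys(rbind(top), num_levels), TRUE, envir = seen)
      out <- matrix(0L, want, num_items)
      got <- 0L
      while (got < want) {
        batch <- max(2L * (want - got), 16L)
        draw <- matrix(
          sample.int(num_levels, batch * num_items, replace = TRUE) - 1L,
          batch, num_items
        )
        keys <- state_keys(draw, num_levels)
        for (b in seq_len(batch)) {
          if (got == want) break
          if (!exists(keys[b], envir = seen, inherits = FALSE)) {
            assign(keys[b], TRUE, envir = seen)
            got <- got + 1L
            out[got, ] <- draw[b, ]
          }
        }
      }
      out
    }
  })
  polim_structure(rbind(bottom, picked, top), n_levels = num_levels)
}

#' Enumerate the full polytomous pattern space
#'
#' All `num_levels^num_items` response patterns in lexicographic order (first
#' item most significant). Refuses to materialize spaces larger than `cap`.
#'
#' @param num_items,num_levels domain size and number of levels.
#' @param cap maximum number of patterns to materialize.
#' @return Integer matrix with `num_levels^num_items` rows.
#' @examples
#' enumerate_patterns(2, 2)
#' @export
enumerate_patterns <- function(num_items, num_levels, cap = 2^20) {
  total <- num_levels^as.double(num_items)
  if (total > cap) {
    stop_input(
      "pattern space has ", format(total, big.mark = ","),
      " points, above the cap of ", format(cap, big.mark = ",")
    )
  }
  total <- as.integer(total)
  r <- seq_len(total) - 1L
  out <- matrix(0L, total, num_items)
  for (q in seq_len(num_items)) {
    out[, q] <- (r %/% num_levels^(num_items - q)) %% num_levels
  }
  colnames(out) <- paste0("q", seq_len(num_items))
  out
}

#' Aggregated polytomous response data
#'
#' Bundles observed response patterns with their frequencies. Duplicate
#' patterns are aggregated; frequencies may be non-integer weights (used by
#' expected-data computations), but must be nonnegative with positive total.
#'
#' @param patterns integer matrix, one respondent (or distinct pattern) per
#'   row.
#' @param freq optional nonnegative frequencies, one per row of `patterns`;
#'   defaults to 1 per row.
#' @param n_levels number of response levels; defaults to `max(patterns) + 1`
#'   (but at least 2).
#' @param items item identifiers.
#' @return An object of class `polim_data`: a list with elements `patterns`
#'   (distinct rows), `freq`, `n_levels`, `items` and `N` (total frequency).
#' @examples
#' polim_data(rbind(c(0, 1), c(0, 1), c(1, 1)))
#' @export
polim_data <- function(patterns, freq = NULL, n_levels = NULL, items = NULL) {
  patterns <- as.matrix(patterns)
  storage.mode(patterns) <- "integer"
  if (nrow(patterns) < 1L) stop_input("no response patterns")
  if (anyNA(patterns) || any(patterns < 0L)) {
    stop_input("response levels must be nonnegative integers")
  }
  if (is.null(n_levels)) n_levels <- max(max(patterns) + 1L, 2L)
  n_levels <- as.integer(n_levels)
  if (any(patterns >= n_levels)) {
    stop_input("response levels must lie in 0..", n_levels - 1L)
  }
  if (is.null(freq)) freq <- rep(1, nrow(patterns))
  if (length(freq) != nrow(patterns) || any(freq < 0) || anyNA(freq)) {
    stop_input("freq must be nonnegative, one value per pattern row")
  }
  if (is.null(items)) items <- colnames(patterns)
  if (is.null(items)) items <- paste0("q", seq_len(ncol(patterns)))
  keys <- state_keys(patterns, n_levels)
  agg <- rowsum(freq, keys, reorder = FALSE)
  upat <- patterns[!duplicated(keys), , drop = FALSE]
  freq <- as.vector(agg[match(
    state_keys(upat, n_levels),
    rownames(agg)
  ), ])
  keep <- freq > 0
  if (!any(keep)) stop_input("total frequency must be positive")
  upat <- upat[keep, , drop = FALSE]
  freq <- freq[keep]
  dimnames(upat) <- list(NULL, items)
  structure(
    list(
      patterns = upat, freq = freq, n_levels = n_levels,
      items = items, N = sum(freq)
    ),
    class = "polim_data"
  )
}

#' @export
print.polim_data <- function(x, ...) {
  cat(
    "Polytomous response data: N = ", format(x$N), ", ",
    nrow(x$patterns), " distinct patterns, ", length(x$items), " items, ",
    x$n_levels, " levels\n",
    sep = ""
  )
  invisible(x)
}

# Expand aggregated data back to one row per respondent (integer freq only).
expand_respondents <- function(data) {
  idx <- rep(seq_len(nrow(data$patterns)), times = round(data$freq))
  data$patterns[idx, , drop = FALSE]
}
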