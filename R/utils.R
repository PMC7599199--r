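# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. `seed = NULL` evaluates in the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

# Derive a per-task seed from a master seed; stays below 2^31 - 1.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 7919 + index * 104729) %% 2147483647)
}

# Encode integer level rows as strings: digit strings for <= 10 levels,
# comma-separated codes otherwise.
state_keys <- function(mat, n_levels) {
  if (n_levels <= 10L) {
    apply(mat, 1L, paste0, collapse = "")
  } else {
    apply(mat, 1L, paste0, collapse = ",")
  }
}

decode_state_key <- function(key, n_levels) {
  if (n_levels <= 10L) {
    as.integer(strsplit(key, "")[[1L]])
  } else {
    as.integer(strsplit(key, ",", fixed = TRUE)[[1L]])
  }
}

stop_input <- function(...) stop(..., call. = FALSE)
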