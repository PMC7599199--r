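# File interfaces: response CSV, structure CSV/JSON, parameter and fit JSON.

#' Read polytomous response data from CSV
#'
#' One respondent per row, one integer-level column per item, mandatory
#' header row of item identifiers. An optional trailing `frequency` column
#' gives pre-aggregated counts. Cells outside `0..n_levels-1` are rejected
#' with the offending row and column named.
#'
#' @param path CSV file path.
#' @param n_levels number of levels; inferred as `max + 1` (at least 2)
#'   when `NULL`.
#' @return A [polim_data].
#' @export
read_response_csv <- function(path, n_levels = NULL) {
  df <- read.csv(path, check.names = FALSE)
  if (nrow(df) < 1L || ncol(df) < 1L) stop_input("empty response file")
  freq <- NULL
  if (tolower(names(df)[ncol(df)]) == "frequency") {
    freq <- df[[ncol(df)]]
    if (any(freq != round(freq)) || any(freq < 0)) {
      stop_input("frequency column must hold nonnegative integers")
    }
    df <- df[, -ncol(df), drop = FALSE]
  }
  mat <- as.matrix(df)
  if (!is.numeric(mat) || any(mat != round(mat)) || anyNA(mat)) {
    bad <- which(is.na(mat) | mat != round(mat), arr.ind = TRUE)[1, ]
    stop_input(
      "non-integer level at row ", bad[1L], ", column '",
      names(df)[bad[2L]], "'"
    )
  }
  if (is.null(n_levels)) n_levels <- max(max(mat) + 1, 2)
  out_of_range <- mat < 0 | mat >= n_levels
  if (any(out_of_range)) {
    bad <- which(out_of_range, arr.ind = TRUE)[1, ]
    stop_input(
      "level ", mat[bad[1L], bad[2L]], " at row ", bad[1L],
      ", column '", names(df)[bad[2L]], "' is outside 0..", n_levels - 1
    )
  }
  polim_data(mat, freq = freq, n_levels = n_levels, items = names(df))
}

#' Read and write structure files
#'
#' CSV: one state per row, one integer-level column per item, header row of
#' item identifiers. JSON: an object with fields `items`, `levels` (the
#' level labels, length = number of levels) and `states` (array of level
#' rows).
#'
#' @param path file path.
#' @param n_levels number of levels; inferred when `NULL` (CSV only).
#' @param structure a [polim_structure].
#' @return The read functions return a [polim_structure]; the write
#'   functions return `path` invisibly.
#' @export
read_structure_csv <- function(path, n_levels = NULL) {
  df <- read.csv(path, check.names = FALSE)
  polim_structure(as.matrix(df), n_levels = n_levels, items = names(df))
}

#' @rdname read_structure_csv
#' @export
write_structure_csv <- function(structure, path) {
  df <- as.data.frame(unclass(structure)[seq_len(nrow(structure)), ,
    drop = FALSE
  ])
  names(df) <- items_of(structure)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_structure_csv
#' @export
read_structure_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  states <- x$states
  if (is.list(states)) states <- do.call(rbind, states)
  polim_structure(as.matrix(states),
    n_levels = length(x$levels),
    items = x$items
  )
}

#' @rdname read_structure_json
#' @export
write_structure_json <- function(structure, path) {
  jsonlite::write_json(
    list(
      items = items_of(structure),
      levels = seq_len(n_levels_of(structure)) - 1L,
      states = unclass(structure)[seq_len(nrow(structure)), , drop = FALSE]
    ),
    path,
    auto_unbox = FALSE, digits = I(17)
  )
  invisible(path)
}

#' Read and write PoLIM parameters as JSON
#'
#' The file carries `items`, `levels`, the per-item error matrices under
#' `epsilon` and the state distribution under `pi`, keyed by state strings
#' (digit strings for at most 10 levels). Probabilities round-trip at full
#' double precision.
#'
#' @param params a [polim_params].
#' @param path file path.
#' @return `read_params_json()` returns a [polim_params];
#'   `write_params_json()` returns `path` invisibly.
#' @export
write_params_json <- function(params, path) {
  st <- params$structure
  keys <- state_keys(st, n_levels_of(st))
  jsonlite::write_json(
    list(
      items = items_of(st),
      levels = seq_len(n_levels_of(st)) - 1L,
      epsilon = params$epsilon,
      pi = as.list(setNames(params$pi, keys))
    ),
    path,
    auto_unbox = TRUE, digits = I(17)
  )
  invisible(path)
}

#' @rdname write_params_json
#' @export
read_params_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  L <- length(x$levels)
  keys <- names(x$pi)
  states <- do.call(rbind, lapply(keys, decode_state_key, n_levels = L))
  st <- polim_structure(states, n_levels = L, items = x$items)
  eps <- lapply(x$epsilon, function(E) matrix(unlist(E), L, L))
  polim_params(eps, as.numeric(unlist(x$pi)), st)
}

fit_schema_version <- "polikst-fit/1"

#' Read and write a fitted model as JSON
#'
#' Serializes a `polim_fit_result` (or the result component of a
#' [polim()] fit): schema version, settings, log-likelihood trace,
#' parameters (full precision) and rates when present. Reading a file with
#' a different schema version is an error.
#'
#' @param result a `polim_fit_result`.
#' @param path file path.
#' @return `read_fit_json()` returns a `polim_fit_result`;
#'   `write_fit_json()` returns `path` invisibly.
#' @export
write_fit_json <- function(result, path) {
  st <- result$params$structure
  keys <- state_keys(st, n_levels_of(st))
  out <- list(
    schema = fit_schema_version,
    settings = result$settings,
    converged = result$converged,
    iterations = result$iterations,
    loglik = result$loglik,
    loglik_trace = result$loglik_trace,
    items = items_of(st),
    levels = seq_len(n_levels_of(st)) - 1L,
    epsilon = result$params$epsilon,
    pi = as.list(setNames(result$params$pi, keys))
  )
  if (!is.null(result$rates)) {
    out$rates <- lapply(result$rates, function(r) {
      list(omega = r$omega, upsilon = r$upsilon)
    })
  }
  jsonlite::write_json(out, path,
    auto_unbox = TRUE, digits = I(17),
    na = "string"
  )
  invisible(path)
}

#' @rdname write_fit_json
#' @export
read_fit_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(x$schema, fit_schema_version)) {
    stop_input(
      "unsupported fit schema '", x$schema, "' (expected ",
      fit_schema_version, ")"
    )
  }
  L <- length(x$levels)
  keys <- names(x$pi)
  states <- do.call(rbind, lapply(keys, decode_state_key, n_levels = L))
  st <- polim_structure(states, n_levels = L, items = x$items)
  eps <- lapply(x$epsilon, function(E) matrix(unlist(E), L, L))
  params <- polim_params(eps, as.numeric(unlist(x$pi)), st)
  rates <- NULL
  if (!is.null(x$rates)) {
    if (is.data.frame(x$rates)) {
      # jsonlite simplifies the per-item list into a two-column frame
      x$rates <- lapply(seq_len(nrow(x$rates)), function(i) {
        list(omega = x$rates$omega[[i]], upsilon = x$rates$upsilon[[i]])
      })
    }
    rates <- lapply(x$rates, function(r) {
      rate_parameters(
        matrix(suppressWarnings(as.numeric(unlist(r$omega))), L, L),
        matrix(suppressWarnings(as.numeric(unlist(r$upsilon))), L, L),
        n_levels = L, strict = FALSE
      )
    })
  }
  res <- new_fit_result(
    params = params, rates = rates,
    trace = as.numeric(x$loglik_trace),
    converged = isTRUE(x$converged), seed = NULL, settings = x$settings
  )
  res$iterations <- x$iterations
  res
}

run_config_keys <- c(
  "seed", "tolerance", "max_iter", "floor", "data", "structure", "out",
  "method", "distance", "partitions", "sizes", "verbosity"
)

#' Read a YAML/JSON run configuration
#'
#' A flat mapping mirroring the command-line flags (`seed`, `tolerance`,
#' `max_iter`, `floor`, `data`, `structure`, `out`, `method`, `distance`,
#' `partitions`, `sizes`, `verbosity`). Unknown keys are rejected with a
#' message naming them.
#'
#' @param path YAML (or JSON) file path.
#' @return Named list of settings.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop_input("run config must be a mapping")
  unknown <- setdiff(names(cfg), run_config_keys)
  if (length(unknown)) {
    stop_input(
      "unknown run-config keys: ", paste(unknown, collapse = ", "),
      " (allowed: ", paste(run_config_keys, collapse = ", "), ")"
    )
  }
  cfg
}
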