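# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single integer", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Input errors get their own condition class so the CLI can map them to
# exit code 2.
stop_input <- function(msg, ...) {
  stop(structure(
    class = c("mm_input_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = NULL)
  ))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Scalar field extraction from a parsed record: NA when absent/null.
scalar_chr <- function(x) {
  if (is.null(x) || length(x) == 0L || all(is.na(x))) NA_character_
  else as.character(x[[1L]])
}
scalar_num <- function(x) {
  if (is.null(x) || length(x) == 0L || all(is.na(x))) NA_real_
  else suppressWarnings(as.numeric(x[[1L]]))
}
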