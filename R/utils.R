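# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Derive independent sub-seeds from a master seed; keeps values in 32-bit
# integer range so downstream set.seed() never overflows.
derive_seed <- function(seed, stream) {
  (as.numeric(seed) * 48271 + stream * 1000003) %% 2147483647
}

stop_field <- function(field, msg) {
  stop(sprintf("invalid configuration field '%s': %s", field, msg),
       call. = FALSE)
}

check_prob <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop_field(field, "must be a probability in [0, 1]")
  invisible(x)
}

check_pos_int <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 ||
      x != round(x))
    stop_field(field, "must be a positive integer")
  invisible(as.integer(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
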