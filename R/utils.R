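# internal helpers shared across modules

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Configuration validation: stop with the offending field named.
check_field <- function(ok, field, what) {
  if (!isTRUE(ok)) {
    stop(sprintf("invalid configuration: field '%s' %s", field, what),
         call. = FALSE)
  }
  invisible(TRUE)
}

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min &&
    x == as.integer(x)
}

is_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

# Derive per-stage seeds from one top-level seed. Documented rule: the
# top-level seed initializes R's RNG once and the stage seeds are the first
# `n` draws from sample.int(.Machine$integer.max - 1L). Stages are therefore
# independently reproducible from (seed, stage index).
stage_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}
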