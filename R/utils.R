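# shared input checks and seed plumbing

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x))
    stop(name, " must be an integer >= ", min, call. = FALSE)
  as.integer(x)
}

check_fraction <- function(x, name, lo = 0, hi = 1, lo_open = FALSE, hi_open = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (if (lo_open) x > lo else x >= lo) && (if (hi_open) x < hi else x <= hi)
  if (!ok) stop(name, " must lie in ", if (lo_open) "(" else "[", lo, ", ", hi,
                if (hi_open) ")" else "]", call. = FALSE)
  as.numeric(x)
}

check_finite_matrix <- function(X, name) {
  if (!is.matrix(X)) stop(name, " must be a matrix", call. = FALSE)
  if (!all(is.finite(X))) stop(name, " contains non-finite values", call. = FALSE)
  invisible(X)
}

# Derive independent sub-seeds from one user seed so that parallel RNG uses
# (weight init, batch shuffling, oversampling draws) do not share a stream.
# Kept below 2^31 - 1.
derive_seeds <- function(seed, n) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, n)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}
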