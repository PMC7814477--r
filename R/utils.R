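# Internal RNG plumbing. A single master seed fans out into named sub-streams
# (init, batch, noise, eval, ...) so that, e.g., changing the evaluation
# cadence never perturbs the training randomness.

# Deterministic 32-bit mix of (master, stream-name, index) into a valid seed.
# Arithmetic in doubles; all intermediates stay below 2^53.
derive_seed <- function(master, stream, index = 0L) {
  ch <- utf8ToInt(stream)
  h <- sum(ch * seq_along(ch)) %% 2147483629
  x <- as.double(master) %% 2147483629
  x <- (x * 48271 + h * 7919 + 104729 * (as.double(index) %% 2147483629)) %% 2147483629
  x <- (x * 69621 + 1) %% 2147483629
  as.integer(x) + 1L
}

# Evaluate expr under a temporary RNG state; the caller's stream is untouched.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar <- function(x, name, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || (positive && x <= 0))
    stop(sprintf("'%s' must be a finite %s scalar", name,
                 if (positive) "positive" else "numeric"), call. = FALSE)
  invisible(x)
}
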