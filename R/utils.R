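#' @keywords internal
"_PACKAGE"

# Deterministic seed derivation. Mixes an arbitrary number of non-negative
# integers into a single seed in [1, 2^31 - 2] so that every source of
# randomness in the package can be traced back to one master seed.
derive_seed <- function(...) {
  parts <- as.numeric(c(...))
  h <- 17
  m <- 2147483629 # prime < 2^31
  for (p in parts) {
    h <- (h * 31 + (p %% m) + 1) %% m
  }
  as.integer(h + 1)
}

# Evaluate `expr` under a locally-set RNG seed, restoring the caller's RNG
# state afterwards so library code never perturbs user-level randomness.
with_seed <- function(seed, expr) {
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
  set.seed(seed)
  expr
}

# round-half-away-from-zero (base round() is banker's rounding)
round_half_up <- function(x) {
  trunc(x + sign(x) * 0.5)
}

# uniform draw of one element from a vector/list (length-1 safe, unlike
# sample(x, 1) which treats numeric scalars as 1:x)
draw_one <- function(x) {
  x[[sample.int(length(x), 1L)]]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
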