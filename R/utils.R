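# internal helpers shared across modules

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so seeded selections never perturb
# an enclosing simulation stream.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

# Deterministic child-seed derivation: one user-facing seed fans out to
# per-module / per-replicate streams.  Constants are from Knuth's LCG; the
# modulus keeps results inside R's 32-bit integer range.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 1103515245 + 12345 * as.numeric(index) + index) %% 2147483647)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Round to the nearest multiple of `unit`, half away from zero (avoids the
# round-to-even surprises of round() at exact midpoints).
round_to <- function(x, unit) floor(x / unit + 0.5) * unit

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

stop_input <- function(...) stop(sprintf(...), call. = FALSE)
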