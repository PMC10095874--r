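# internal helpers shared across modules

# Round half away from zero (commercial rounding). base::round() rounds half
# to even, which is wrong for reported whole-percent changes.
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Deterministic per-layer sub-seed: one scenario seed fans out into
# independent streams so adding a layer never perturbs the others.
# Kept strictly below 2^31 - 1.
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer((abs(seed) %% 40000L) * 48271 + 7919 * stream) %% 2147483647L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_encar <- function(...) stop(sprintf(...), call. = FALSE)
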