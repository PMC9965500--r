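# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

# Deterministic sub-seed derivation so one user seed drives every
# stochastic stage without the stages sharing a stream.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(offset) * 104729) %% 2147483587)
}

# Round half away from zero (base round() is banker's).
round_half_up <- function(x) floor(x + 0.5)

# Truncate (never round) a ratio to 2 decimals, as benchmark tables
# conventionally print imbalance ratios.  The 1e-9 nudge protects exact
# ratios (e.g. 1.15) from downward floating-point error.
truncate2 <- function(x) {
  sprintf("%.2f", floor(x * 100 + 1e-9) / 100)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
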