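# Internal helpers shared across modules.

# Derive a reproducible 32-bit stage seed from a global seed and a stage name,
# so each pipeline stage draws from an independent but reproducible stream.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% 2147483647
  as.integer((abs(seed) * 7919 + h) %% 2147483647)
}

# Run `expr` under a local RNG seeded with `seed`, restoring the caller's
# RNG state afterwards so library code never perturbs user randomness.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

# Column-wise softmax of a matrix (each column normalized over rows).
col_softmax <- function(m) {
  mx <- apply(m, 2L, max)
  e <- exp(sweep(m, 2L, mx, "-"))
  sweep(e, 2L, colSums(e), "/")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
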