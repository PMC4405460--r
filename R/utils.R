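# Internal helpers shared across modules.

# Evaluate expr under a local RNG seed, restoring the caller's RNG state.
# seed = NULL means: use (and advance) the current RNG stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministically derive n child seeds (< 2^31) from a master seed.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Inverse-CDF draw from Exponential(rate) truncated to [lo, hi); hi may be Inf.
rtrunc_exp <- function(n, rate, lo, hi = Inf) {
  u <- stats::runif(n)
  plo <- exp(-rate * lo)
  phi <- if (is.finite(hi)) exp(-rate * hi) else 0
  -log(plo - u * (plo - phi)) / rate
}

# Mean of Exponential(rate) truncated to [lo, hi).
mean_trunc_exp <- function(rate, lo, hi = Inf) {
  if (!is.finite(hi)) return(lo + 1 / rate)
  plo <- exp(-rate * lo)
  phi <- exp(-rate * hi)
  1 / rate + (lo * plo - hi * phi) / (plo - phi)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
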