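# Internal helpers: deterministic seed derivation and scoped RNG.

# Evaluate `code` under a fixed seed without disturbing the caller's RNG
# stream. All stochastic generator internals go through this.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Derive a child seed (< 2^31) from a master seed and a string key using a
# 32-bit FNV-1a hash. Doubles represent all integers below 2^53 exactly, so
# the modular arithmetic below is exact.
derive_seed <- function(master, ...) {
  key <- paste(c(format(master), ...), collapse = "/")
  h <- 2166136261
  for (b in utf8ToInt(key)) {
    h <- bitwXor_dbl(h, b)
    h <- (h * 16777619) %% 4294967296
  }
  as.integer((h + master) %% 2147483647) + 1L
}

# xor of a double-held 32-bit value with a small int
bitwXor_dbl <- function(a, b) {
  lo <- a %% 2^16
  hi <- (a - lo) / 2^16
  bitwXor(as.integer(lo), as.integer(b)) + hi * 2^16
}

as_utc <- function(x) {
  if (inherits(x, "POSIXct")) return(as.POSIXct(format(x, tz = "UTC"), tz = "UTC"))
  as.POSIXct(x, tz = "UTC")
}

# truncated-normal sampler (lower bound only), deterministic via runif
rnorm_trunc <- function(n, mean, sd, lower = 0) {
  if (sd <= 0) return(pmax(rep(mean, n), lower))
  plo <- pnorm(lower, mean, sd)
  qnorm(runif(n, plo, 1), mean, sd)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
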