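# Internal numerical and validation helpers.

# log(sum(exp(x))) without overflow; -Inf-safe.
logsumexp <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(x - m)))
}

# log(exp(a) - exp(b)) for a >= b; returns -Inf when the difference
# underflows (numerically b >= a).
logdiffexp <- function(a, b) {
  if (b >= a) return(-Inf)
  a + log1p(-exp(b - a))
}

stopifnot_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0 || x >= 1)
    stop(sprintf("'%s' must be a single number in (0, 1)", name), call. = FALSE)
  invisible(x)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards so library code does not disturb user
# simulations.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    set.seed(as.integer(seed))
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else rm(".Random.seed", envir = globalenv())
    }, add = TRUE)
  }
  expr
}

# rank-based inverse normal transform with average ties
inverse_normal <- function(x) {
  out <- rep(NA_real_, length(x))
  ok <- !is.na(x)
  n <- sum(ok)
  if (n > 0L) out[ok] <- qnorm((rank(x[ok], ties.method = "average") - 0.5) / n)
  out
}
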