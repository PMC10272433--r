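`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_that <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) stopf(fmt, ...)
  invisible(TRUE)
}

# Derive a reproducible 31-bit sub-seed from a root seed and an index.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 16807) %% 2147483647)
}

# Moments of a normal distribution truncated to [a, b]: standardized
# truncated mean m and variance v plus the moments on the original scale.
truncnorm_moments <- function(a, b, mu, sigma) {
  al <- (a - mu) / sigma
  be <- (b - mu) / sigma
  Z <- pnorm(be) - pnorm(al)
  assert_that(Z > 1e-12, "truncation interval [%g, %g] has no mass", a, b)
  m <- (dnorm(al) - dnorm(be)) / Z
  v <- 1 + (al * dnorm(al) - be * dnorm(be)) / Z - m^2
  list(m = m, v = v, mean = mu + sigma * m, var = sigma^2 * v, mass = Z)
}

# Inverse-CDF sampler for a truncated normal.
rtrunc_norm <- function(n, mu, sigma, a = -Inf, b = Inf) {
  lo <- pnorm((a - mu) / sigma)
  hi <- pnorm((b - mu) / sigma)
  mu + sigma * qnorm(runif(n, lo, hi))
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x >= 0 && x == round(x)
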