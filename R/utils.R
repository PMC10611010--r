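#' Round half away from zero
#'
#' Decimal rounding with ties going away from zero (the convention used by the
#' source tables), unlike [round()]'s round-half-even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded to `digits` decimals, ties away from zero.
#' @examples
#' round_half_up(28.1425, 3)
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# format a number half-up with fixed decimals
fmt_num <- function(x, digits = 3) {
  formatC(round_half_up(x, digits), format = "f", digits = digits)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# derive a per-stage seed from a master seed; stays within 32-bit range
stage_seed <- function(seed, k) {
  as.integer((as.numeric(seed) + 9973 * k) %% .Machine$integer.max)
}

# quantile function of a normal truncated below at 0
qnorm_trunc0 <- function(u, mu, sigma) {
  p0 <- pnorm(0, mean = mu, sd = sigma)
  qnorm(p0 + u * (1 - p0), mean = mu, sd = sigma)
}

# location mu* such that a N(mu*, sigma) truncated below at 0 has mean m
# (truncation shifts the mean up; honour the configured mean exactly)
trunc0_location <- function(m, sigma) {
  if (m <= 0) stop("target mean must be > 0")
  etrunc <- function(mu) mu + sigma * stats::dnorm(mu / sigma) /
    pnorm(mu / sigma)
  if (etrunc(m) - m < 1e-12 * m) return(m)  # truncation negligible
  stats::uniroot(function(mu) etrunc(mu) - m,
                 lower = m - 20 * sigma, upper = m,
                 tol = 1e-12)$root
}

# quantile function of a normal truncated to [lo, hi]
qnorm_trunc <- function(u, mu, sigma, lo, hi) {
  plo <- pnorm(lo, mu, sigma)
  phi <- pnorm(hi, mu, sigma)
  qnorm(plo + u * (phi - plo), mu, sigma)
}
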