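#' Zero-truncated Gaussian sampling and moments
#'
#' Module durations are modelled as a Gaussian with the negative tail
#' removed: the duration distribution is the normal distribution conditioned
#' on being non-negative (a skewed, non-symmetrical distribution with no
#' probability atom at zero). `rnorm_trunc0()` samples it by inverse-CDF on
#' a uniform stream restricted to `[pnorm(0, mu, sigma), 1]`, which draws
#' from exactly the same distribution as rejection sampling of the negative
#' tail. `tnorm0_mean()` is the closed-form mean
#' `mu + sigma * dnorm(mu/sigma) / pnorm(mu/sigma)`.
#'
#' @param n number of draws.
#' @param mu,sigma Gaussian location and scale (seconds); `sigma = 0` gives
#'   the constant `mu` (which must then be non-negative).
#' @return `rnorm_trunc0()`: numeric vector of non-negative draws;
#'   `tnorm0_mean()`, `tnorm0_var()`: numeric scalars.
#' @examples
#' mean(rnorm_trunc0(1e4, 100, 80))
#' tnorm0_mean(100, 80)
#' @export
rnorm_trunc0 <- function(n, mu, sigma) {
  stopifnot(sigma >= 0)
  if (sigma == 0) {
    stopifnot(mu >= 0)
    return(rep(mu, n))
  }
  lo <- stats::pnorm(0, mean = mu, sd = sigma)
  u <- lo + (1 - lo) * stats::runif(n)
  stats::qnorm(u, mean = mu, sd = sigma)
}

#' @rdname rnorm_trunc0
#' @export
tnorm0_mean <- function(mu, sigma) {
  if (sigma == 0) return(mu)
  d <- mu / sigma
  mu + sigma * stats::dnorm(d) / stats::pnorm(d)
}

#' @rdname rnorm_trunc0
#' @export
tnorm0_var <- function(mu, sigma) {
  if (sigma == 0) return(0)
  d <- mu / sigma
  lambda <- stats::dnorm(d) / stats::pnorm(d)
  sigma^2 * (1 - d * lambda - lambda^2)
}

# Location parameter of a zero-truncated Gaussian with scale `sigma` whose
# truncated mean equals `target`. Used by the synthetic generator so that
# generated sample means reproduce the published table means.
calibrate_tnorm0_mu <- function(target, sigma) {
  if (sigma == 0 || target <= 0) return(target)
  f <- function(mu) tnorm0_mean(mu, sigma) - target
  lower <- target - 20 * sigma
  while (f(lower) > 0) lower <- lower - 20 * sigma
  stats::uniroot(f, c(lower, target), tol = 1e-8)$root
}

# Round half away from zero (platform-independent occurrence rounding).
round_half_up <- function(x) floor(x + 0.5)
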