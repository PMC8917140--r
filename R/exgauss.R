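#' The ex-Gaussian distribution
#'
#' Density, distribution function and random generation for the ex-Gaussian
#' distribution: the sum of a Gaussian with mean `mu` and standard deviation
#' `sigma` and an independent exponential with mean `tau`. In stop-signal
#' modelling it describes both go reaction times and the latent stop latency
#' (SSRT) distribution, whose Gaussian component captures the leading edge and
#' whose exponential component captures the right tail.
#'
#' The density is
#' \deqn{f(x) = \frac{1}{\tau}\exp\!\Big(\frac{\sigma^2}{2\tau^2} -
#'   \frac{x-\mu}{\tau}\Big)\,
#'   \Phi\!\Big(\frac{x-\mu}{\sigma} - \frac{\sigma}{\tau}\Big)}
#' with mean \eqn{\mu + \tau} and variance \eqn{\sigma^2 + \tau^2}.
#' All computations are carried out on the log scale for stability.
#'
#' @param x vector of quantiles (same time unit as `mu`, `sigma`, `tau`;
#'   milliseconds throughout this package).
#' @param n number of draws.
#' @param mu Gaussian component mean.
#' @param sigma Gaussian component standard deviation, > 0.
#' @param tau exponential component mean, > 0.
#' @param log,log.p logical; return log density / log probability.
#' @return `dexgauss` the density, `pexgauss` the CDF, `rexgauss` `n` draws.
#'   Arguments recycle as usual.
#' @examples
#' dexgauss(150, mu = 109, sigma = 36, tau = 34)
#' mean(rexgauss(1e4, mu = 109, sigma = 36, tau = 34))  # ~ mu + tau = 143
#' @export
dexgauss <- function(x, mu, sigma, tau, log = FALSE) {
  check_exgauss_params(sigma, tau)
  lf <- -base::log(tau) + sigma^2 / (2 * tau^2) - (x - mu) / tau +
    stats::pnorm((x - mu) / sigma - sigma / tau, log.p = TRUE)
  if (log) lf else exp(lf)
}

#' @rdname dexgauss
#' @export
pexgauss <- function(x, mu, sigma, tau, log.p = FALSE) {
  check_exgauss_params(sigma, tau)
  u <- (x - mu) / sigma
  # F(x) = Phi(u) - exp(sigma^2/(2 tau^2) - (x - mu)/tau) Phi(u - sigma/tau)
  tail_log <- sigma^2 / (2 * tau^2) - (x - mu) / tau +
    stats::pnorm(u - sigma / tau, log.p = TRUE)
  p <- stats::pnorm(u) - exp(tail_log)
  p[x == -Inf] <- 0
  p[x == Inf] <- 1
  p <- pmin(pmax(p, 0), 1)
  if (log.p) base::log(p) else p
}

#' @rdname dexgauss
#' @export
rexgauss <- function(n, mu, sigma, tau) {
  check_exgauss_params(sigma, tau)
  if (n == 0) return(numeric(0))
  stats::rnorm(n, mean = mu, sd = sigma) + stats::rexp(n, rate = 1 / tau)
}

check_exgauss_params <- function(sigma, tau) {
  if (any(sigma <= 0)) stop("ex-Gaussian `sigma` must be > 0", call. = FALSE)
  if (any(tau <= 0)) stop("ex-Gaussian `tau` must be > 0", call. = FALSE)
  invisible(TRUE)
}
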