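#' Parameter containers for the generative models
#'
#' `exgauss_params()`, `race_params()` and `ddm_params()` build validated
#' parameter lists for, respectively, an ex-Gaussian RT distribution, the
#' stop-signal horse race with trigger failures (TF, the probability that the
#' stop process is never launched on a stop trial) and go failures (GF, the
#' probability of an omission on the go side), and the four-parameter diffusion
#' decision model of the Go task.
#'
#' Times are in milliseconds at the interface. For the diffusion model the
#' within-trial noise standard deviation is fixed at `s = 1` with time measured
#' in seconds, the scaling convention under which boundary separations around
#' 1.3--1.8 and drift rates around 1--4 are natural magnitudes.
#'
#' @param mu,sigma,tau ex-Gaussian location (ms), Gaussian SD (ms, > 0) and
#'   exponential mean (ms, > 0).
#' @param go,stop `exgauss_params` for the go RT and stop latency distributions.
#' @param tf,gf trigger-failure and go-failure probabilities in \[0, 1\].
#' @param max_rt response deadline in ms; go RTs beyond it are omissions.
#' @param a boundary separation (a.u., > 0).
#' @param v drift rate towards the correct (upper) boundary, per second.
#' @param t0 non-decision time in ms, >= 0.
#' @param z relative starting point in (0, 1); 0.5 is unbiased.
#' @param s within-trial diffusion noise SD; fixed convention 1.
#' @return a list of class `"exgauss_params"`, `"race_params"` or
#'   `"ddm_params"`.
#' @examples
#' race_params(go = exgauss_params(361, 63, 85),
#'             stop = exgauss_params(109, 36, 34), tf = 0.05, gf = 0.003)
#' ddm_params(a = 1.78, v = 4, t0 = 224, z = 0.51)
#' @export
exgauss_params <- function(mu, sigma, tau) {
  stopifnot(is.numeric(mu), length(mu) == 1, is.finite(mu))
  check_exgauss_params(sigma, tau)
  structure(list(mu = mu, sigma = sigma, tau = tau), class = "exgauss_params")
}

#' @rdname exgauss_params
#' @export
race_params <- function(go, stop, tf = 0, gf = 0, max_rt = 1200) {
  stopifnot(inherits(go, "exgauss_params"), inherits(stop, "exgauss_params"))
  if (tf < 0 || tf > 1) base::stop("`tf` must be in [0, 1]", call. = FALSE)
  if (gf < 0 || gf > 1) base::stop("`gf` must be in [0, 1]", call. = FALSE)
  if (max_rt <= 0) base::stop("`max_rt` must be positive", call. = FALSE)
  structure(list(go = go, stop = stop, tf = tf, gf = gf, max_rt = max_rt),
            class = "race_params")
}

#' @rdname exgauss_params
#' @export
ddm_params <- function(a, v, t0, z = 0.5, s = 1) {
  if (a <= 0) stop("boundary separation `a` must be > 0", call. = FALSE)
  if (z <= 0 || z >= 1) stop("starting point `z` must be in (0, 1)", call. = FALSE)
  if (t0 < 0) stop("non-decision time `t0` must be >= 0", call. = FALSE)
  if (s <= 0) stop("noise SD `s` must be > 0", call. = FALSE)
  structure(list(a = a, v = v, t0 = t0, z = z, s = s), class = "ddm_params")
}

#' @export
print.exgauss_params <- function(x, ...) {
  cat(sprintf("ex-Gaussian(mu = %.4g, sigma = %.4g, tau = %.4g) [ms]\n",
              x$mu, x$sigma, x$tau))
  invisible(x)
}

#' @export
print.race_params <- function(x, ...) {
  cat("Stop-signal race parameters\n")
  cat(sprintf("  go   : mu = %.4g, sigma = %.4g, tau = %.4g ms\n",
              x$go$mu, x$go$sigma, x$go$tau))
  cat(sprintf("  stop : mu = %.4g, sigma = %.4g, tau = %.4g ms\n",
              x$stop$mu, x$stop$sigma, x$stop$tau))
  cat(sprintf("  tf = %.3g, gf = %.3g, max_rt = %g ms\n", x$tf, x$gf, x$max_rt))
  invisible(x)
}

#' @export
print.ddm_params <- function(x, ...) {
  cat(sprintf(
    "DDM(a = %.4g, v = %.4g, t0 = %.4g ms, z = %.4g, s = %g)\n",
    x$a, x$v, x$t0, x$z, x$s))
  invisible(x)
}
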