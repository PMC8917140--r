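#' One differential-evolution MCMC step
#'
#' Each chain proposes `x' = x + gamma * (x_a - x_b) + e`, where `x_a`, `x_b`
#' are the states of two distinct other chains from the supplied population
#' and `e` is small uniform jitter, and accepts by the Metropolis rule. With
#' `gamma = 2.38 / sqrt(2 d)` the proposal self-tunes to the shape of the
#' target as the population spreads over it.
#'
#' @param state numeric matrix `n_chains x d` of current chain states.
#' @param log_target function taking a state matrix and returning the vector
#'   of log target densities.
#' @param lp current log target values (recomputed when `NULL`).
#' @param gamma scale of the difference vector; default `2.38 / sqrt(2 d)`.
#' @param jitter half-width of the uniform jitter (default 1e-3).
#' @return list with updated `state`, `lp`, and logical `accepted`.
#' @export
de_mcmc_step <- function(state, log_target, lp = NULL, gamma = NULL,
                         jitter = 1e-3) {
  n <- nrow(state); d <- ncol(state)
  if (n < 3) stop("DE-MCMC needs at least 3 chains", call. = FALSE)
  if (is.null(gamma)) gamma <- 2.38 / sqrt(2 * d)
  if (is.null(lp)) lp <- log_target(state)
  prop <- de_propose(state, state, gamma, jitter)
  lp_new <- log_target(prop)
  acc <- base::log(stats::runif(n)) < lp_new - lp
  acc[!is.finite(lp_new)] <- FALSE
  state[acc, ] <- prop[acc, , drop = FALSE]
  lp[acc] <- lp_new[acc]
  list(state = state, lp = lp, accepted = acc)
}

# DE crossover proposals for every row of `state`, with donors drawn from
# `pool` (the previous-generation population).
de_propose <- function(state, pool, gamma, jitter) {
  n <- nrow(state); d <- ncol(state)
  ab <- vapply(seq_len(n), function(i) sample(seq_len(n)[-i], 2L), integer(2))
  state + gamma * (pool[ab[1, ], , drop = FALSE] - pool[ab[2, ], , drop = FALSE]) +
    matrix(stats::runif(n * d, -jitter, jitter), n, d)
}

#' Sample a target density with DE-MCMC
#'
#' Plain (non-hierarchical) differential-evolution MCMC, mainly used to
#' validate the sampler on analytically known targets.
#'
#' @param log_target vectorised log density: takes an `n x d` matrix, returns
#'   length-`n` vector.
#' @param init `n_chains x d` matrix of starting states.
#' @param n_iter iterations to retain (after `n_burn`).
#' @param n_burn burn-in iterations to discard.
#' @param gamma,jitter see [de_mcmc_step()].
#' @param seed optional integer seed.
#' @return array `[n_chains, n_iter, d]` of retained states, with the
#'   acceptance rate in attribute `"acceptance"`.
#' @examples
#' tgt <- function(x) -0.5 * rowSums(x^2)  # standard normal
#' s <- de_mcmc(tgt, matrix(rnorm(15), 15, 1), n_iter = 200, seed = 1)
#' @export
de_mcmc <- function(log_target, init, n_iter, n_burn = 0, gamma = NULL,
                    jitter = 1e-3, seed = NULL) {
  with_seed(seed, {
    state <- as.matrix(init)
    n <- nrow(state); d <- ncol(state)
    lp <- log_target(state)
    out <- array(NA_real_, c(n, n_iter, d))
    n_acc <- 0
    for (it in seq_len(n_burn + n_iter)) {
      stp <- de_mcmc_step(state, log_target, lp, gamma, jitter)
      state <- stp$state; lp <- stp$lp
      if (it > n_burn) {
        out[, it - n_burn, ] <- state
        n_acc <- n_acc + sum(stp$accepted)
      }
    }
    attr(out, "acceptance") <- n_acc / (n * n_iter)
    out
  })
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Split-free R-hat from between- and within-chain variances:
#' with `m` chains of length `n`, `W` the mean within-chain variance and `B/n`
#' the variance of chain means, \eqn{\hat R = \sqrt{((n-1)/n\,W + B/n)/W}}.
#' Values near 1 indicate the chains sample the same distribution.
#'
#' @param chains a matrix `[n_chains, n_iter]`, or a 3-d array
#'   `[n_chains, n_iter, n_par]` for several parameters.
#' @return scalar (matrix input) or named vector (array input). Zero
#'   within-chain variance gives `NA` (undefined), not 1.
#' @export
gelman_rubin <- function(chains) {
  if (length(dim(chains)) == 3)
    return(apply(chains, 3, gelman_rubin))
  stopifnot(is.matrix(chains))
  m <- nrow(chains); n <- ncol(chains)
  if (m < 2 || n < 2) stop("need >= 2 chains and >= 2 iterations", call. = FALSE)
  W <- mean(apply(chains, 1, stats::var))
  B_over_n <- stats::var(rowMeans(chains))
  if (W <= 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B_over_n) / W)
}

#' Effective sample size of MCMC draws
#'
#' Autocorrelation-adjusted number of independent draws, computed from the
#' multi-chain variogram estimate of the lag correlations with Geyer's
#' initial-positive-sequence truncation:
#' \eqn{ESS = mn / (1 + 2\sum_t \hat\rho_t)}, capped at the total number of
#' retained draws.
#'
#' @inheritParams gelman_rubin
#' @return scalar or named vector. A constant chain set returns `NA`.
#' @export
effective_sample_size <- function(chains) {
  if (length(dim(chains)) == 3)
    return(apply(chains, 3, effective_sample_size))
  stopifnot(is.matrix(chains))
  m <- nrow(chains); n <- ncol(chains)
  W <- mean(apply(chains, 1, stats::var))
  B_over_n <- if (m > 1) stats::var(rowMeans(chains)) else 0
  var_plus <- (n - 1) / n * W + B_over_n
  if (!is.finite(var_plus) || var_plus <= 0) return(NA_real_)
  rho <- numeric(n - 1)
  for (t in seq_len(n - 1)) {
    Vt <- mean((chains[, (t + 1):n, drop = FALSE] -
                  chains[, 1:(n - t), drop = FALSE])^2)
    rho[t] <- 1 - Vt / (2 * var_plus)
  }
  # Geyer initial positive sequence on paired sums
  s <- 0
  t <- 1
  while (t + 1 <= length(rho)) {
    pair <- rho[t] + rho[t + 1]
    if (pair < 0) break
    s <- s + pair
    t <- t + 2
  }
  ess <- m * n / (1 + 2 * s)
  min(ess, m * n)
}
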