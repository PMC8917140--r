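#' Wiener first-passage-time density
#'
#' Defective first-passage density of the two-boundary diffusion decision
#' process at decision time `t` (ms), for the upper (`a`) or lower (0)
#' boundary. Under accuracy coding the upper boundary is the correct
#' response. The density uses the classic pair of series representations of
#' the scaled density -- a small-time expansion over mirrored Gaussian terms
#' and a large-time Fourier sine series -- choosing per evaluation whichever
#' needs fewer terms for a truncation error below `eps`.
#'
#' Integrated over all `t`, the upper and lower densities sum to the
#' closed-form absorption probabilities returned by
#' [ddm_absorption_prob()], and to 1 jointly.
#'
#' @param t decision time(s) in ms (response time minus `t0`), > 0.
#' @param params a [ddm_params()] (its `t0` is not applied here; `t` is
#'   already a decision time).
#' @param boundary `"upper"` or `"lower"`.
#' @param log return log density.
#' @param eps truncation error budget per evaluation (default 1e-7).
#' @return density per ms (defective: integrates to the boundary's absorption
#'   probability).
#' @examples
#' p <- ddm_params(a = 1.78, v = 4, t0 = 224, z = 0.51)
#' wiener_fpt_density(300, p, "upper")
#' @export
wiener_fpt_density <- function(t, params, boundary = c("upper", "lower"),
                               log = FALSE, eps = 1e-7) {
  stopifnot(inherits(params, "ddm_params"))
  boundary <- match.arg(boundary)
  if (any(t <= 0)) stop("decision time `t` must be > 0", call. = FALSE)
  n <- length(t)
  ld <- wiener_ld_vec(t / 1000, rep(params$a / params$s, n),
                      rep(params$v / params$s, n), rep(params$z, n),
                      upper = boundary == "upper", eps = eps)
  ld <- ld - base::log(1000)  # per-second density -> per-ms
  if (log) ld else exp(ld)
}

# Vectorised log density (per second) of absorption at time td (seconds).
# a, v in unit-noise scaling; w = relative start; upper selects the boundary.
wiener_ld_vec <- function(td, a, v, w, upper, eps = 1e-7) {
  stopifnot(length(td) == length(a), length(td) == length(v),
            length(td) == length(w))
  if (length(upper) == 1) upper <- rep(upper, length(td))
  # reflect for the upper boundary
  if (any(upper)) {
    v[upper] <- -v[upper]
    w[upper] <- 1 - w[upper]
  }
  u <- td / a^2  # scaled time
  out <- rep(-Inf, length(td))
  ok <- is.finite(u) & u > 0
  if (!any(ok)) return(out)
  uu <- u[ok]
  # Series term counts for truncation error eps on the scaled density.
  squ <- sqrt(uu)
  ks <- rep(2, length(uu))
  i1 <- 2 * sqrt(2 * pi) * squ * eps < 1
  ks[i1] <- pmax(2 + sqrt(-2 * uu[i1] *
                            base::log(2 * eps * sqrt(2 * pi * uu[i1]))),
                 squ[i1] + 1)
  kl <- 1 / (pi * squ)
  i2 <- pi * uu * eps < 1
  kl[i2] <- pmax(sqrt(-2 * base::log(pi * uu[i2] * eps) / (pi^2 * uu[i2])),
                 kl[i2])
  use_small <- ks < kl
  g <- numeric(length(uu))
  ww <- w[ok]
  if (any(use_small)) {
    us <- uu[use_small]; ws <- ww[use_small]
    K <- ceiling(max(ks[use_small]))
    kk <- seq(-floor((K - 1) / 2), ceiling((K - 1) / 2))
    acc <- 0
    for (k in kk)
      acc <- acc + (ws + 2 * k) * exp(-(ws + 2 * k)^2 / (2 * us))
    g[use_small] <- acc / sqrt(2 * pi * us^3)
  }
  if (any(!use_small)) {
    ul <- uu[!use_small]; wl <- ww[!use_small]
    K <- ceiling(max(kl[!use_small]))
    acc <- 0
    for (k in seq_len(K))
      acc <- acc + k * exp(-k^2 * pi^2 * ul / 2) * sin(k * pi * wl)
    g[!use_small] <- pi * acc
  }
  lg <- rep(-Inf, length(g))
  pos <- g > 0
  lg[pos] <- base::log(g[pos])
  out[ok] <- lg - v[ok] * a[ok] * ww - v[ok]^2 * td[ok] / 2 - 2 * base::log(a[ok])
  out
}

#' Closed-form absorption probabilities of the diffusion process
#'
#' Probability that the diffusion starting at `z * a` is absorbed at the
#' upper boundary `a` rather than at 0:
#' \deqn{P(\mathrm{upper}) = \frac{1 - e^{-2 v a z / s^2}}{1 - e^{-2 v a / s^2}}}
#' (equal to `z` when `v = 0`).
#'
#' @inheritParams wiener_fpt_density
#' @return absorption probability for the requested boundary.
#' @examples
#' ddm_absorption_prob(ddm_params(a = 1.78, v = 4, t0 = 224, z = 0.51))
#' @export
ddm_absorption_prob <- function(params, boundary = c("upper", "lower")) {
  stopifnot(inherits(params, "ddm_params"))
  boundary <- match.arg(boundary)
  p_up <- absorption_upper(params$a / params$s, params$v / params$s, params$z)
  if (boundary == "upper") p_up else 1 - p_up
}

absorption_upper <- function(a, v, z) {
  ifelse(abs(v * a) < 1e-10, z, expm1(-2 * v * a * z) / expm1(-2 * v * a))
}

# P(decision time <= T ms) at a boundary, by Gauss-Legendre quadrature of the
# defective density. Vectorised over parameter rows (a, v, z in unit-noise
# scaling, T in ms).
wiener_cdf_rows <- function(T_ms, a, v, z, upper, n_nodes = 128) {
  m <- length(a)
  gl <- gauss_legendre(n_nodes, 1e-9, T_ms / 1000)
  nodes <- gl$x; wq <- gl$w
  ld <- wiener_ld_vec(rep(nodes, each = m), rep(a, length(nodes)),
                      rep(v, length(nodes)), rep(z, length(nodes)),
                      upper = upper)
  dens <- matrix(exp(ld), nrow = m)
  pmin(pmax(as.vector(dens %*% wq), 0), 1)
}

#' Go-trial log-likelihood under the diffusion model
#'
#' Accuracy-coded four-parameter DDM likelihood for one go trial, with a
#' go-failure mixture for omissions. Correct responses map to the upper
#' boundary and errors to the lower; a responded trial contributes
#' `(1 - gf)` times the Wiener density at `rt - t0`, and an omitted trial
#' (`rt = NA`) contributes `gf + (1 - gf) * P(decision time > max_rt - t0)`.
#'
#' @param correct logical; was the response correct? Ignored for omissions.
#' @param rt response time in ms, or `NA` for an omission.
#' @param params a [ddm_params()].
#' @param gf go-failure (omission) mixture probability.
#' @param max_rt response deadline, ms.
#' @param coding `"accuracy"` (correct = upper, the default) or `"response"`
#'   (right = upper), in which case `correct` is interpreted as "responded
#'   right".
#' @return log-likelihood contribution. A responded trial with `rt <= t0` is
#'   impossible under the model and yields `-Inf` with a warning.
#' @examples
#' loglik_go_trial(TRUE, 450, ddm_params(a = 1.78, v = 4, t0 = 224, z = 0.51))
#' @export
loglik_go_trial <- function(correct, rt, params, gf = 0, max_rt = 1200,
                            coding = c("accuracy", "response")) {
  stopifnot(inherits(params, "ddm_params"))
  coding <- match.arg(coding)
  n <- max(length(correct), length(rt))
  correct <- rep_len(correct, n); rt <- rep_len(rt, n)
  out <- numeric(n)
  resp <- !is.na(rt)
  if (any(resp)) {
    dtms <- rt[resp] - params$t0
    bad <- dtms <= 0
    if (any(bad))
      warning("responded trial(s) with rt <= t0: impossible under the model (-Inf)")
    ld <- rep(-Inf, sum(resp))
    if (any(!bad)) {
      up <- correct[resp][!bad]
      dd <- dtms[!bad]
      tmp <- numeric(length(dd))
      if (any(up)) tmp[up] <- wiener_fpt_density(dd[up], params, "upper", log = TRUE)
      if (any(!up)) tmp[!up] <- wiener_fpt_density(dd[!up], params, "lower", log = TRUE)
      ld[!bad] <- tmp
    }
    out[resp] <- base::log(pmax(1 - gf, 0)) + ld
  }
  if (any(!resp)) {
    p_in <- ddm_decision_cdf(max_rt - params$t0, params)
    out[!resp] <- base::log(pmax(gf + (1 - gf) * (1 - p_in), 1e-300))
  }
  out
}

# P(decision time <= T_ms) across both boundaries, integrating the density
# piecewise so that long horizons do not starve the early mass of nodes.
ddm_decision_cdf <- function(T_ms, params) {
  if (T_ms <= 0) return(0)
  breaks <- unique(pmin(c(0, 2000, 10000, T_ms), T_ms))
  a <- params$a / params$s; v <- params$v / params$s
  total <- 0
  for (i in seq_len(length(breaks) - 1)) {
    gl <- gauss_legendre(48, breaks[i] + 1e-9, breaks[i + 1])
    n <- length(gl$x)
    dens <- exp(wiener_ld_vec(rep(gl$x, 2) / 1000, rep(a, 2 * n),
                              rep(v, 2 * n), rep(params$z, 2 * n),
                              upper = rep(c(TRUE, FALSE), each = n))) / 1000
    total <- total + sum((dens[1:n] + dens[n + 1:n]) * gl$w)
  }
  min(total, 1)
}

# Condense a single-cell go-trial data.frame for the DDM likelihood.
ddm_data_prep <- function(records, max_rt, coding = "accuracy") {
  go <- records[records$trial_type == "go", ]
  resp <- go[go$response != "none" & !is.na(go$rt_ms), ]
  upper <- if (coding == "accuracy") resp$correct else resp$response == "right"
  list(rt_upper = resp$rt_ms[upper], rt_lower = resp$rt_ms[!upper],
       n_omit = sum(go$response == "none"), n_go = nrow(go),
       p_correct = if (nrow(resp)) mean(resp$correct) else NA_real_,
       mean_rt = if (nrow(resp)) mean(resp$rt_ms) else NA_real_,
       var_rt = if (nrow(resp) > 1) stats::var(resp$rt_ms) else NA_real_,
       max_rt = max_rt)
}

# Vectorised DDM log-likelihood over parameter rows.
# theta columns: a, v, t0(ms), z, gf (natural scale).
ddm_ll_mat <- function(theta, dat) {
  m <- nrow(theta)
  a <- theta[, 1]; v <- theta[, 2]; t0 <- theta[, 3]
  z <- theta[, 4]; gf <- theta[, 5]
  ll <- base::log(pmax(1 - gf, 0)) *
    (length(dat$rt_upper) + length(dat$rt_lower))
  k_up <- length(dat$rt_upper); k_lo <- length(dat$rt_lower)
  if (k_up + k_lo > 0) {
    rts <- c(dat$rt_upper, dat$rt_lower)
    k <- k_up + k_lo
    dt_s <- (rep(rts, each = m) - rep(t0, k)) / 1000
    ldm <- rep(-Inf, m * k)
    pos <- dt_s > 0
    if (any(pos)) {
      up <- rep(c(rep(TRUE, k_up), rep(FALSE, k_lo)), each = m)
      ldm[pos] <- wiener_ld_vec(dt_s[pos], rep(a, k)[pos], rep(v, k)[pos],
                                rep(z, k)[pos], upper = up[pos]) -
        base::log(1000)
    }
    ll <- ll + rowSums(matrix(ldm, nrow = m))
  }
  if (dat$n_omit > 0) {
    # P(decision within the deadline) per row; integration horizons differ
    # with t0, so substitute u = t/T onto a fixed [0, 1] Gauss-Legendre grid
    # and evaluate every (row, node) in one vectorised call
    nn <- 48
    gl <- gauss_legendre(nn, 0, 1)
    Tdec <- (dat$max_rt - t0) / 1000
    p_in <- numeric(m)
    ok <- Tdec > 0
    if (any(ok)) {
      mo <- sum(ok)
      tt <- rep(gl$x, each = mo) * rep(Tdec[ok], nn)
      aa <- rep(a[ok], nn); vv <- rep(v[ok], nn); zz <- rep(z[ok], nn)
      dens <- exp(wiener_ld_vec(tt, aa, vv, zz, upper = TRUE)) +
        exp(wiener_ld_vec(tt, aa, vv, zz, upper = FALSE))
      p_in[ok] <- pmin(as.vector(matrix(dens, mo) %*% gl$w) * Tdec[ok], 1)
    }
    ll <- ll + dat$n_omit * base::log(pmax(gf + (1 - gf) * (1 - p_in), 1e-300))
  }
  ll
}

#' Posterior-predictive summaries of a fitted diffusion model
#'
#' Simulates the fitted four-parameter DDM forward and summarises predicted
#' accuracy and mean RTs, for comparison against observed go-task summaries.
#'
#' @param params a [ddm_params()].
#' @param n number of simulated trials (default 1e5).
#' @param dt_ms Euler step passed to [simulate_ddm_trials()].
#' @param seed optional integer seed.
#' @return list with `p_correct`, `mean_rt_correct`, `mean_rt_error` (ms).
#' @export
fit_ddm_summary <- function(params, n = 1e5, dt_ms = 0.1, seed = NULL) {
  d <- simulate_ddm_trials(params, n = n, dt_ms = dt_ms, seed = seed)
  d <- d[!d$censored, ]
  up <- d$boundary == "upper"
  list(p_correct = mean(up),
       mean_rt_correct = if (any(up)) mean(d$rt_ms[up]) else NA_real_,
       mean_rt_error = if (any(!up)) mean(d$rt_ms[!up]) else NA_real_)
}
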