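#' Log-likelihood terms of the ex-Gaussian race model
#'
#' Analytic likelihood of the independent horse-race model of stopping with
#' ex-Gaussian go and stop (SSRT) distributions and two mixture probabilities:
#' trigger failures (`tf`, the stop process is never launched) and go failures
#' (`gf`, the go process is omitted). Observed RT support is `(0, max_rt]`.
#'
#' The four observable trial kinds contribute:
#' \itemize{
#'   \item go response at `rt`: \eqn{(1-gf)\,f_{go}(rt)}
#'   \item go omission: \eqn{gf + (1-gf)\,(1 - F_{go}(max\_rt))}
#'   \item signal-respond at `rt` given `ssd`:
#'     \eqn{(1-gf)\,f_{go}(rt)\,[tf + (1-tf)(1 - F_{stop}(rt-ssd))]}
#'   \item successful stop given `ssd`: one minus the total signal-respond
#'     mass, i.e. \eqn{1-(1-gf)\int_0^{max\_rt} f_{go}(t)\,[tf +
#'     (1-tf)(1-F_{stop}(t-ssd))]\,dt}, evaluated by 48-node Gauss-Legendre
#'     quadrature (machine-precision accurate for these smooth integrands;
#'     validated against adaptive quadrature).
#' }
#' A stop trial without a response is scored as a successful stop regardless
#' of whether the go process was omitted, raced and lost, or ran past the
#' deadline: those events are observationally indistinguishable, so the `gf`
#' and deadline mass sits inside the stop-success probability. The stop
#' ex-Gaussian keeps its full support; negative stop latencies are handled by
#' the survival function as-is.
#'
#' @param rt response time, ms, in `(0, max_rt]`.
#' @param ssd stop-signal delay, ms, >= 0.
#' @param params a [race_params()].
#' @return log-likelihood contribution (log density per ms for responded
#'   trials, log probability otherwise).
#' @seealso [dataset_loglik()] for whole-dataset sums,
#'   [simulate_race_trials()] for the matching simulator.
#' @examples
#' p <- race_params(go = exgauss_params(361, 63, 85),
#'                  stop = exgauss_params(109, 36, 34), tf = 0.05, gf = 0.003)
#' loglik_go_response(446, p)
#' exp(loglik_successful_stop(250, p))  # P(no response | stop trial, ssd = 250)
#' @export
loglik_go_response <- function(rt, params) {
  stopifnot(inherits(params, "race_params"))
  if (any(rt <= 0 | rt > params$max_rt))
    stop("`rt` outside (0, max_rt]", call. = FALSE)
  race_ll_mat(race_theta(params),
              list(go_rt = rt, n_go_omit = 0L, sr_rt = numeric(0),
                   sr_ssd = numeric(0), inh_ssd = numeric(0),
                   max_rt = params$max_rt),
              per_trial = "go")
}

#' @rdname loglik_go_response
#' @export
loglik_go_omission <- function(params) {
  stopifnot(inherits(params, "race_params"))
  th <- race_theta(params)
  s_go <- 1 - pexgauss(params$max_rt, th[1], th[2], th[3])
  base::log(th[8] + (1 - th[8]) * s_go)
}

#' @rdname loglik_go_response
#' @export
loglik_signal_respond <- function(rt, ssd, params) {
  stopifnot(inherits(params, "race_params"))
  if (any(rt <= 0 | rt > params$max_rt))
    stop("`rt` outside (0, max_rt]", call. = FALSE)
  if (any(ssd < 0)) stop("`ssd` must be >= 0", call. = FALSE)
  th <- race_theta(params)
  lgo <- dexgauss(rt, th[1], th[2], th[3], log = TRUE)
  surv <- 1 - pexgauss(rt - ssd, th[4], th[5], th[6])
  base::log(1 - th[8]) + lgo + base::log(th[7] + (1 - th[7]) * surv)
}

#' @rdname loglik_go_response
#' @export
loglik_successful_stop <- function(ssd, params) {
  base::log(race_success_prob(ssd, params))
}

#' Probability of a successful stop at a given delay
#'
#' @inheritParams loglik_go_response
#' @return probability that a stop trial at delay `ssd` ends without a
#'   response.
#' @export
race_success_prob <- function(ssd, params) {
  stopifnot(inherits(params, "race_params"))
  if (any(ssd < 0)) stop("`ssd` must be >= 0", call. = FALSE)
  th <- matrix(race_theta(params), nrow = 1)
  vapply(ssd, function(s) {
    1 - race_sr_mass_mat(th, s, params$max_rt)[1]
  }, numeric(1))
}

#' Race-model log-likelihood of a trial dataset
#'
#' Sums the per-trial race-model terms over a set of trial records from a
#' single participant, task and condition. Responded go trials and
#' signal-respond trials contribute densities; go omissions and no-response
#' stop trials contribute the corresponding probabilities. `-Inf` propagates.
#'
#' @param records a trial data.frame as produced by [run_session()] /
#'   [read_trials()], restricted to one participant x task x condition cell.
#' @param params a [race_params()].
#' @return scalar log-likelihood (0 for an empty record set).
#' @examples
#' p <- race_params(go = exgauss_params(361, 63, 85),
#'                  stop = exgauss_params(109, 36, 34), tf = 0.05, gf = 0.003)
#' trials <- run_session(session_config("classical", "control"), p, seed = 1)
#' dataset_loglik(trials, p)
#' @export
dataset_loglik <- function(records, params) {
  stopifnot(inherits(params, "race_params"))
  if (nrow(records) == 0) return(0)
  cells <- unique(records[c("participant_id", "task", "condition")])
  if (nrow(cells) > 1)
    stop("`records` must come from a single participant x task x condition cell",
         call. = FALSE)
  dat <- race_data_prep(records, params$max_rt)
  race_ll_mat(matrix(race_theta(params), nrow = 1), dat)[1]
}

race_theta <- function(params) {
  c(params$go$mu, params$go$sigma, params$go$tau,
    params$stop$mu, params$stop$sigma, params$stop$tau,
    params$tf, params$gf)
}

# Condense a single-cell trial data.frame into the sufficient pieces for the
# likelihood: responded-go RTs, go-omission count, signal-respond (rt, ssd)
# pairs, and a table of no-response stop-trial SSDs.
race_data_prep <- function(records, max_rt) {
  go <- records[records$trial_type == "go", ]
  st <- records[records$trial_type == "stop", ]
  go_resp <- go[go$response != "none" & !is.na(go$rt_ms), ]
  sr <- st[st$response != "none" & !is.na(st$rt_ms), ]
  inh <- st[st$response == "none", ]
  inh_tab <- if (nrow(inh)) table(inh$ssd_ms) else table(numeric(0))
  list(go_rt = go_resp$rt_ms,
       n_go_omit = sum(go$response == "none"),
       sr_rt = sr$rt_ms, sr_ssd = sr$ssd_ms,
       inh_ssd = as.numeric(names(inh_tab)), inh_n = as.integer(inh_tab),
       n_go = nrow(go), n_stop = nrow(st),
       p_inhib = if (nrow(st)) nrow(inh) / nrow(st) else NA_real_,
       mean_ssd = if (nrow(st)) mean(st$ssd_ms) else NA_real_,
       max_rt = max_rt)
}

# Total signal-respond probability mass at each ssd, per parameter row.
# theta columns: mu_go, sigma_go, tau_go, mu_stop, sigma_stop, tau_stop, tf, gf.
# Returns a matrix [nrow(theta) x length(ssd)].
race_sr_mass_mat <- function(theta, ssd, max_rt, n_nodes = 48) {
  m <- nrow(theta)
  k <- length(ssd)
  gl <- gauss_legendre(n_nodes, 0, max_rt)
  nodes <- gl$x; w <- gl$w
  # f_go at nodes: m x n_nodes (independent of ssd)
  fgo <- matrix(dexgauss(rep(nodes, each = m), theta[, 1], theta[, 2], theta[, 3]),
                nrow = m)
  # stop CDF at node - ssd for every (chain, node, ssd) in one call
  xs <- rep(rep(nodes, each = m), times = k) - rep(ssd, each = m * n_nodes)
  fs <- array(pexgauss(xs, theta[, 4], theta[, 5], theta[, 6]),
              dim = c(m, n_nodes, k))
  out <- matrix(NA_real_, m, k)
  for (j in seq_len(k)) {
    integrand <- fgo * (theta[, 7] + (1 - theta[, 7]) * (1 - fs[, , j]))
    out[, j] <- (1 - theta[, 8]) * as.vector(integrand %*% w)
  }
  if (any(!is.finite(out)))
    stop("quadrature failure in race stop-success probability", call. = FALSE)
  out
}

# Vectorised race log-likelihood over parameter rows for one prepared dataset.
# per_trial = "go" returns the per-trial go-response contributions instead of
# the dataset sum (internal convenience for the public scalar wrappers).
race_ll_mat <- function(theta, dat, per_trial = NULL) {
  if (!is.matrix(theta)) theta <- matrix(theta, nrow = 1)
  m <- nrow(theta)
  tf <- theta[, 7]; gf <- theta[, 8]
  l1mgf <- base::log(pmax(1 - gf, 0))
  ll <- numeric(m)
  if (length(dat$go_rt)) {
    lgo <- matrix(dexgauss(rep(dat$go_rt, each = m),
                           theta[, 1], theta[, 2], theta[, 3], log = TRUE),
                  nrow = m)
    if (identical(per_trial, "go")) return(as.vector(l1mgf + t(lgo)))
    ll <- ll + length(dat$go_rt) * l1mgf + rowSums(lgo)
  } else if (identical(per_trial, "go")) {
    return(numeric(0))
  }
  if (dat$n_go_omit > 0) {
    s_go <- 1 - pexgauss(dat$max_rt, theta[, 1], theta[, 2], theta[, 3])
    ll <- ll + dat$n_go_omit * base::log(pmax(gf + (1 - gf) * s_go, 1e-300))
  }
  if (length(dat$sr_rt)) {
    k <- length(dat$sr_rt)
    lgo <- matrix(dexgauss(rep(dat$sr_rt, each = m),
                           theta[, 1], theta[, 2], theta[, 3], log = TRUE),
                  nrow = m)
    fs <- matrix(pexgauss(rep(dat$sr_rt - dat$sr_ssd, each = m),
                          theta[, 4], theta[, 5], theta[, 6]), nrow = m)
    lstop <- base::log(pmax(tf + (1 - tf) * (1 - fs), 1e-300))
    ll <- ll + k * l1mgf + rowSums(lgo) + rowSums(lstop)
  }
  if (length(dat$inh_ssd)) {
    p_succ <- 1 - race_sr_mass_mat(theta, dat$inh_ssd, dat$max_rt)
    ll <- ll + as.vector(base::log(pmax(p_succ, 1e-300)) %*% dat$inh_n)
  }
  ll
}
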