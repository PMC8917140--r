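# Hierarchical Bayesian estimation by differential-evolution MCMC, in the
# style of crossover-based samplers for evidence-accumulation models: each
# chain carries all subject-level parameter blocks plus the group-level
# (location, scale) block; subject blocks are updated by DE crossover against
# the same block in the other chains, conditional on the chain's current
# group parameters, and the group block is updated conditional on the subject
# parameters (the data likelihood cancels there).
#
# All sampling happens on a transformed scale: log for positive parameters,
# probit for probabilities. Subject-level distributions are normal on that
# scale; group locations have normal hyperpriors and group scales half-normal
# hyperpriors.

race_par_names <- c("mu_go", "sigma_go", "tau_go",
                    "mu_stop", "sigma_stop", "tau_stop", "tf", "gf")
ddm_par_names <- c("a", "v", "t0", "z", "gf")

race_model_spec <- function(max_rt = 1200) {
  list(
    model = "race",
    par_names = race_par_names,
    links = c(rep("log", 6), "probit", "probit"),
    loc_m0 = c(log(400), log(60), log(80), log(150), log(35), log(40), -1.8, -2.5),
    loc_s0 = c(0.6, 0.8, 0.8, 0.8, 0.4, 0.4, 1.0, 1.0),
    scale_hn = rep(0.5, 8),
    extra_blocks = list(c(4L, 5L, 6L, 7L), c(7L, 8L)),
    n_full = 1L, n_asis = 2L, n_joint = 1L,
    data_prep = function(records) race_data_prep(records, max_rt),
    loglik = function(theta_nat, dat) race_ll_mat(theta_nat, dat),
    init = function(dat) {
      m <- mean(dat$go_rt); sdev <- max(stats::sd(dat$go_rt), 20)
      tau_g <- 0.8 * sdev
      ssrt0 <- if (length(dat$go_rt) && is.finite(dat$p_inhib)) {
        q <- 1 - dat$p_inhib
        rts <- sort(dat$go_rt)
        rts[max(1L, ceiling(q * length(rts)))] - dat$mean_ssd
      } else 150
      ssrt0 <- min(max(ssrt0, 80), 400)
      omit <- dat$n_go_omit / max(dat$n_go, 1)
      c(mu_go = max(m - tau_g, 50), sigma_go = 0.6 * sdev, tau_go = tau_g,
        mu_stop = 0.7 * ssrt0, sigma_stop = 0.2 * ssrt0, tau_stop = 0.3 * ssrt0,
        tf = 0.03, gf = min(max(omit, 0.002), 0.2))
    })
}

ddm_model_spec <- function(max_rt = 1200, coding = "accuracy") {
  list(
    model = "ddm",
    par_names = ddm_par_names,
    links = c("log", "identity", "log", "probit", "probit"),
    loc_m0 = c(log(1.5), 2, log(200), 0, -2.5),
    loc_s0 = c(0.5, 2.0, 0.6, 0.3, 1.0),
    scale_hn = c(0.5, 1.5, 0.5, 0.25, 0.5),
    extra_blocks = list(c(1L, 4L)),
    n_full = 1L, n_asis = 2L, burn_cycles = 2L,
    data_prep = function(records) ddm_data_prep(records, max_rt, coding),
    loglik = function(theta_nat, dat) ddm_ll_mat(theta_nat, dat),
    init = function(dat) {
      ez <- ez_diffusion(dat$p_correct, dat$mean_rt, dat$var_rt,
                         n = length(dat$rt_upper) + length(dat$rt_lower))
      omit <- dat$n_omit / max(dat$n_go, 1)
      c(a = ez$a, v = ez$v, t0 = ez$t0, z = 0.5,
        gf = min(max(omit, 0.002), 0.2))
    })
}

# EZ-diffusion method-of-moments starting values (unit-noise scaling).
# p: accuracy, mrt mean RT (ms), vrt RT variance (ms^2), n trial count.
ez_diffusion <- function(p, mrt, vrt, n) {
  p <- min(max(p, 0.5 + 1 / (2 * max(n, 2))), 1 - 1 / (2 * max(n, 2)))
  L <- stats::qlogis(p)
  vrt_s <- max(vrt, 100) / 1e6  # ms^2 -> s^2
  x <- L * (L * p^2 - L * p + p - 0.5) / vrt_s
  v <- sign(p - 0.5) * x^(1 / 4)
  v <- min(max(v, 0.3), 8)
  a <- min(max(L / v, 0.5), 4)
  y <- -v * a
  mdt <- (a / (2 * v)) * (1 - exp(y)) / (1 + exp(y))
  t0 <- min(max(mrt - 1000 * mdt, 50), 600)
  list(a = a, v = v, t0 = t0)
}

link_to_nat <- function(x, links) {
  for (j in seq_along(links)) {
    x[, j] <- switch(links[j], log = exp(x[, j]),
                     probit = stats::pnorm(x[, j]), identity = x[, j])
  }
  x
}

link_to_trans <- function(x, links) {
  for (j in seq_along(links)) {
    x[, j] <- switch(links[j], log = base::log(x[, j]),
                     probit = stats::qnorm(pmin(pmax(x[, j], 1e-12), 1 - 1e-12)),
                     identity = x[, j])
  }
  x
}

# log hyperprior of the group block phi = (loc, scale): rows = chains.
hyper_lprior <- function(phi, spec) {
  d <- length(spec$par_names)
  loc <- phi[, 1:d, drop = FALSE]
  sc <- phi[, d + 1:d, drop = FALSE]
  lp <- rowSums(stats::dnorm(loc, rep(spec$loc_m0, each = nrow(phi)),
                             rep(spec$loc_s0, each = nrow(phi)), log = TRUE))
  bad <- rowSums(sc <= 0) > 0
  lps <- rowSums(stats::dnorm(sc, 0, rep(spec$scale_hn, each = nrow(phi)),
                              log = TRUE))
  out <- lp + lps + base::log(2) * ncol(sc)
  out[bad] <- -Inf
  out
}

# log subject-level prior density of transformed theta rows under phi rows.
subj_lprior <- function(theta, phi, spec) {
  d <- length(spec$par_names)
  loc <- phi[, 1:d, drop = FALSE]
  sc <- phi[, d + 1:d, drop = FALSE]
  out <- rowSums(stats::dnorm(theta, loc, pmax(sc, 1e-300), log = TRUE))
  out[rowSums(sc <= 0) > 0] <- -Inf
  out
}

#' Fit the hierarchical race or diffusion model
#'
#' `fit_race()` estimates the ex-Gaussian race model with trigger and go
#' failures (8 subject-level parameters); `fit_ddm()` estimates the
#' accuracy-coded four-parameter diffusion model of the Go task plus a
#' go-failure probability (5 subject-level parameters). Both fit one task x
#' condition cell at a time, hierarchically across participants, by
#' differential-evolution MCMC: 33 chains by default, 500 burn-in iterations
#' (with 5% migration probability during burn-in only) and 120 retained
#' iterations per chain, mirroring common practice for these models.
#'
#' @param records trial data.frame covering one task x condition cell for
#'   several participants (see [run_session()], [generate_study()],
#'   [read_trials()]).
#' @param n_chains number of DE-MCMC chains (>= 3; default 33).
#' @param n_keep retained iterations per chain after burn-in (default 120).
#' @param n_burn burn-in iterations (default 500).
#' @param migration_prob probability of a chain-migration step per burn-in
#'   iteration (default 0.05).
#' @param max_rt response deadline in ms used by the likelihoods.
#' @param coding (`fit_ddm`) `"accuracy"` maps correct responses to the upper
#'   boundary (default); `"response"` maps right responses to it.
#' @param seed integer seed; fits are exactly reproducible given the seed.
#' @param progress print a progress line every 100 iterations.
#' @return an object of class `c("race_fit"/"ddm_fit", "ss_hfit")` with
#'   retained samples, per-parameter R-hat and effective sample sizes.
#'   See [summary.ss_hfit()], [coef.ss_hfit()], [plot.ss_hfit()].
#' @examples
#' \donttest{
#' bp <- study_blueprint(n_participants = 4, seed = 1)
#' study <- generate_study(bp)
#' cell <- subset(study$trials, task == "classical" & condition == "control")
#' fit <- fit_race(cell, n_chains = 12, n_keep = 30, n_burn = 60, seed = 1)
#' summary(fit)
#' }
#' @export
fit_race <- function(records, n_chains = 33, n_keep = 120, n_burn = 500,
                     migration_prob = 0.05, max_rt = 1200, seed = NULL,
                     progress = FALSE) {
  fit <- hier_fit(records, race_model_spec(max_rt), n_chains, n_keep, n_burn,
                  migration_prob, seed, progress)
  class(fit) <- c("race_fit", "ss_hfit")
  fit
}

#' @rdname fit_race
#' @export
fit_ddm <- function(records, n_chains = 33, n_keep = 120, n_burn = 500,
                    migration_prob = 0.05, max_rt = 1200,
                    coding = c("accuracy", "response"), seed = NULL,
                    progress = FALSE) {
  coding <- match.arg(coding)
  fit <- hier_fit(records, ddm_model_spec(max_rt, coding), n_chains, n_keep,
                  n_burn, migration_prob, seed, progress)
  class(fit) <- c("ddm_fit", "ss_hfit")
  fit
}

hier_fit <- function(records, spec, n_chains, n_keep, n_burn, migration_prob,
                     seed, progress = FALSE,
                     burn_cycles = spec$burn_cycles %||% 3L) {
  if (n_chains < 3) stop("need >= 3 chains for DE crossover", call. = FALSE)
  cells <- unique(records[c("task", "condition")])
  if (nrow(cells) > 1)
    stop("fit one task x condition cell at a time", call. = FALSE)
  subj_ids <- sort(unique(records$participant_id))
  subj_data <- lapply(subj_ids, function(id)
    spec$data_prep(records[records$participant_id == id, ]))
  names(subj_data) <- subj_ids
  S <- length(subj_data)
  d <- length(spec$par_names)
  gamma_s <- 2.38 / sqrt(2 * d)
  gamma_h <- 2.38 / sqrt(2 * 2 * d)
  jit <- 1e-3

  with_seed(seed, {
    # --- initialization: jittered method-of-moments starts -----------------
    theta <- array(NA_real_, c(n_chains, S, d))
    ll <- matrix(NA_real_, n_chains, S)
    for (s in seq_len(S)) {
      base_t <- link_to_trans(matrix(spec$init(subj_data[[s]]), 1), spec$links)
      for (attempt in seq_len(60)) {
        need <- if (attempt == 1) seq_len(n_chains) else which(!is.finite(ll[, s]))
        if (!length(need)) break
        theta[need, s, ] <- matrix(rep(base_t, each = length(need)),
                                   length(need), d) +
          matrix(stats::rnorm(length(need) * d, 0, 0.25), length(need), d)
        ll[need, s] <- spec$loglik(
          link_to_nat(matrix(theta[need, s, ], length(need), d), spec$links),
          subj_data[[s]])
      }
      if (any(!is.finite(ll[, s])))
        stop(sprintf("could not find finite-likelihood start values for subject %s",
                     subj_ids[s]), call. = FALSE)
    }
    loc0 <- apply(theta, 3, function(m) mean(m))
    sc0 <- pmax(apply(theta, 3, function(m) stats::sd(as.vector(m))), 0.05)
    phi <- cbind(matrix(rep(loc0, each = n_chains), n_chains, d) +
                   matrix(stats::rnorm(n_chains * d, 0, 0.05), n_chains, d),
                 matrix(rep(sc0, each = n_chains), n_chains, d) *
                   exp(matrix(stats::rnorm(n_chains * d, 0, 0.1), n_chains, d)))
    lp_hyper <- hyper_lprior(phi, spec)
    lp_theta <- matrix(NA_real_, n_chains, S)
    for (s in seq_len(S))
      lp_theta[, s] <- subj_lprior(matrix(theta[, s, ], n_chains, d), phi, spec)

    keep_theta <- array(NA_real_, c(n_chains, n_keep, S, d))
    keep_phi <- array(NA_real_, c(n_chains, n_keep, 2 * d))

    n_total <- n_burn + n_keep
    for (it in seq_len(n_total)) {
      n_cycles <- if (it <= n_burn) burn_cycles else 1L
      for (cycle in seq_len(n_cycles)) {
      # migration (burn-in only)
      if (it <= n_burn && stats::runif(1) < migration_prob) {
        k <- sample(2:max(2, floor(n_chains / 2)), 1)
        who <- sample(n_chains, k)
        full <- rowSums(ll) + rowSums(lp_theta) + lp_hyper
        from <- who[c(k, seq_len(k - 1))]  # ring: chain who[j] offered who[j-1]'s state
        accept <- base::log(stats::runif(k)) < full[from] - full[who]
        src <- from[accept]; dst <- who[accept]
        if (length(dst)) {
          theta[dst, , ] <- theta[src, , ]
          phi[dst, ] <- phi[src, ]
          ll[dst, ] <- ll[src, ]
          lp_theta[dst, ] <- lp_theta[src, ]
          lp_hyper[dst] <- lp_hyper[src]
        }
      }
      # --- group block -------------------------------------------------
      # Per parameter: exact Gibbs draw of the group location (normal
      # subject-level model and normal hyperprior are conjugate given the
      # scale), then a 1-d DE-Metropolis update of the group scale against
      # its half-normal hyperprior.
      for (j in seq_len(d)) {
        th_j <- matrix(theta[, , j], n_chains, S)  # chains x subjects
        sc_j <- phi[, d + j]
        prec <- S / sc_j^2 + 1 / spec$loc_s0[j]^2
        mu_post <- (rowSums(th_j) / sc_j^2 + spec$loc_m0[j] / spec$loc_s0[j]^2) / prec
        phi[, j] <- stats::rnorm(n_chains, mu_post, 1 / sqrt(prec))
        # scale update
        dev2 <- rowSums((th_j - phi[, j])^2)
        sc_lp <- function(sc) {
          out <- rep(-Inf, length(sc))
          ok <- sc > 0
          out[ok] <- -S * base::log(sc[ok]) - dev2[ok] / (2 * sc[ok]^2) +
            stats::dnorm(sc[ok], 0, spec$scale_hn[j], log = TRUE)
          out
        }
        prop <- de_propose(matrix(sc_j, ncol = 1), matrix(sc_j, ncol = 1),
                           2.38 / sqrt(2), jit)[, 1]
        acc <- base::log(stats::runif(n_chains)) < sc_lp(prop) - sc_lp(sc_j)
        phi[acc, d + j] <- prop[acc]
      }
      lp_hyper <- hyper_lprior(phi, spec)
      for (s in seq_len(S))
        lp_theta[, s] <- subj_lprior(matrix(theta[, s, ], n_chains, d), phi, spec)
      # --- subject blocks ----------------------------------------------
      # Full-block crossover sweeps plus sub-block sweeps over weakly
      # identified parameter subsets (stop-side parameters trade off against
      # TF; narrower blocks raise acceptance along those ridges).
      blocks <- c(rep(list(seq_len(d)), spec$n_full), spec$extra_blocks)
      for (b in blocks) for (s in seq_len(S)) {
        cur <- matrix(theta[, s, ], n_chains, d)
        g <- if (stats::runif(1) < 0.1) 0.98 else
          stats::runif(1, 0.5, 1) * 2.38 / sqrt(2 * length(b))
        prop <- cur
        prop[, b] <- de_propose(cur[, b, drop = FALSE],
                                cur[, b, drop = FALSE], g, jit)
        ll_new <- spec$loglik(link_to_nat(prop, spec$links), subj_data[[s]])
        lp_new <- subj_lprior(prop, phi, spec)
        acc <- base::log(stats::runif(n_chains)) <
          (ll_new + lp_new) - (ll[, s] + lp_theta[, s])
        acc[!is.finite(ll_new + lp_new)] <- FALSE
        if (any(acc)) {
          theta[acc, s, ] <- prop[acc, , drop = FALSE]
          ll[acc, s] <- ll_new[acc]
          lp_theta[acc, s] <- lp_new[acc]
        }
      }
      # --- interweaved non-centered group moves ------------------------
      # Holding the standardized subject deviations fixed, propose a joint
      # (location, scale) change that rigidly translates/rescales all
      # subjects of one parameter. The subject-prior and Jacobian terms
      # cancel, leaving the data likelihood and hyperprior ratios; this move
      # walks the slow shared-ridge direction that per-subject crossover
      # cannot.
      for (j in sample.int(d, min(spec$n_asis, d))) {
        loc_j <- phi[, j]; sc_j <- phi[, d + j]
        pair <- cbind(loc_j, sc_j)
        pp <- de_propose(pair, pair, 2.38 / 2, jit)
        okp <- pp[, 2] > 0
        eta <- (matrix(theta[, , j], n_chains, S) - loc_j) / sc_j  # chains x subjects
        th_new <- pp[, 1] + pp[, 2] * eta
        ll_new <- matrix(-Inf, n_chains, S)
        for (s in seq_len(S)) {
          prop <- matrix(theta[, s, ], n_chains, d)
          prop[, j] <- th_new[, s]
          if (any(okp))
            ll_new[okp, s] <- spec$loglik(
              link_to_nat(prop[okp, , drop = FALSE], spec$links),
              subj_data[[s]])[seq_len(sum(okp))]
        }
        dh <- stats::dnorm(pp[, 1], spec$loc_m0[j], spec$loc_s0[j], log = TRUE) -
          stats::dnorm(loc_j, spec$loc_m0[j], spec$loc_s0[j], log = TRUE) +
          stats::dnorm(pp[, 2], 0, spec$scale_hn[j], log = TRUE) -
          stats::dnorm(sc_j, 0, spec$scale_hn[j], log = TRUE)
        acc <- base::log(stats::runif(n_chains)) <
          rowSums(ll_new) - rowSums(ll) + dh
        acc[!okp | !is.finite(rowSums(ll_new))] <- FALSE
        if (any(acc)) {
          phi[acc, j] <- pp[acc, 1]
          phi[acc, d + j] <- pp[acc, 2]
          theta[acc, , j] <- th_new[acc, , drop = FALSE]
          ll[acc, ] <- ll_new[acc, , drop = FALSE]
        }
      }
      lp_hyper <- hyper_lprior(phi, spec)
      for (s in seq_len(S))
        lp_theta[, s] <- subj_lprior(matrix(theta[, s, ], n_chains, d),
                                     phi, spec)
      # --- joint full-state crossover ----------------------------------
      # One proposal moves every subject block and the group block together,
      # with the step built from whole-state population differences: this is
      # the move that travels coherent group-plus-subjects ridges (e.g. the
      # whole cohort trading stop-side shape parameters at fixed mean).
      for (jm in seq_len(spec$n_joint %||% 0L)) {
        X <- cbind(matrix(theta, n_chains, S * d), phi)
        g <- if (stats::runif(1) < 0.1) 0.98 else
          stats::runif(1, 0.5, 1) * 2.38 / sqrt(2 * ncol(X))
        prop <- de_propose(X, X, g, jit)
        th_p <- array(prop[, seq_len(S * d)], c(n_chains, S, d))
        phi_p <- prop[, S * d + seq_len(2 * d), drop = FALSE]
        lp_h_new <- hyper_lprior(phi_p, spec)
        ll_new <- matrix(-Inf, n_chains, S)
        lp_t_new <- matrix(-Inf, n_chains, S)
        for (s in seq_len(S)) {
          ll_new[, s] <- spec$loglik(
            link_to_nat(matrix(th_p[, s, ], n_chains, d), spec$links),
            subj_data[[s]])
          lp_t_new[, s] <- subj_lprior(matrix(th_p[, s, ], n_chains, d),
                                       phi_p, spec)
        }
        tot_new <- rowSums(ll_new) + rowSums(lp_t_new) + lp_h_new
        acc <- base::log(stats::runif(n_chains)) <
          tot_new - (rowSums(ll) + rowSums(lp_theta) + lp_hyper)
        acc[!is.finite(tot_new)] <- FALSE
        if (any(acc)) {
          theta[acc, , ] <- th_p[acc, , , drop = FALSE]
          phi[acc, ] <- phi_p[acc, , drop = FALSE]
          ll[acc, ] <- ll_new[acc, , drop = FALSE]
          lp_theta[acc, ] <- lp_t_new[acc, , drop = FALSE]
          lp_hyper[acc] <- lp_h_new[acc]
        }
      }
      }
      if (it > n_burn) {
        keep_theta[, it - n_burn, , ] <- theta
        keep_phi[, it - n_burn, ] <- phi
      }
      if (progress && it %% 100 == 0)
        message(sprintf("iteration %d / %d", it, n_total))
    }

    # --- diagnostics on the sampling (transformed) scale -------------------
    par_labels <- c(as.vector(outer(spec$par_names, subj_ids,
                                    function(p, s) paste(s, p, sep = "."))),
                    paste0("loc.", spec$par_names),
                    paste0("scale.", spec$par_names))
    flat <- array(NA_real_, c(n_chains, n_keep, S * d + 2 * d))
    k <- 0
    for (s in seq_len(S)) for (j in seq_len(d)) {
      k <- k + 1
      flat[, , k] <- keep_theta[, , s, j]
    }
    flat[, , S * d + seq_len(2 * d)] <- keep_phi
    dimnames(flat)[[3]] <- par_labels
    rhat <- gelman_rubin(flat)
    ess <- effective_sample_size(flat)

    structure(list(model = spec$model, par_names = spec$par_names,
                   links = spec$links, subjects = subj_ids,
                   task = cells$task[1], condition = cells$condition[1],
                   samples_theta = keep_theta, samples_phi = keep_phi,
                   n_chains = n_chains, n_keep = n_keep, n_burn = n_burn,
                   rhat = rhat, ess = ess, subj_data = subj_data,
                   seed = seed, call = sys.call(-1)),
              class = "ss_hfit")
  })
}

#' Posterior summaries of a hierarchical fit
#'
#' Subject-level parameters are summarised on the natural scale (ms for
#' times, probabilities for `tf`/`gf`/`z`, a.u. otherwise): posterior mean,
#' SD and central 95% interval per subject and parameter. The group rows
#' report the across-subject mean of the subject posterior means -- the
#' quantity a descriptive group table prints -- plus posterior summaries of
#' the group-level location and scale on the sampling scale.
#'
#' @param fit an `ss_hfit`.
#' @param percent report `tf`/`gf` as percentages (default TRUE).
#' @param check_convergence error when any R-hat exceeds 1.1 unless
#'   overridden (default TRUE; set `FALSE` to summarise anyway).
#' @return list with data.frames `subjects`, `group` and `hyper`.
#' @export
posterior_summary <- function(fit, percent = TRUE, check_convergence = TRUE) {
  stopifnot(inherits(fit, "ss_hfit"))
  bad <- fit$rhat[is.finite(fit$rhat) & fit$rhat > 1.1]
  if (check_convergence && length(bad))
    stop(sprintf("%d parameter(s) have R-hat > 1.1 (max %.3f); pass check_convergence = FALSE to summarise anyway",
                 length(bad), max(bad)), call. = FALSE)
  d <- length(fit$par_names)
  S <- length(fit$subjects)
  rows <- list()
  post_means <- matrix(NA_real_, S, d, dimnames = list(fit$subjects, fit$par_names))
  for (s in seq_len(S)) {
    nat <- link_to_nat(matrix(fit$samples_theta[, , s, ],
                              fit$n_chains * fit$n_keep, d), fit$links)
    nat <- scale_percent(nat, fit$par_names, percent)
    post_means[s, ] <- colMeans(nat)
    rows[[s] ] <- data.frame(
      subject = fit$subjects[s], parameter = fit$par_names,
      mean = colMeans(nat), sd = apply(nat, 2, stats::sd),
      q2.5 = apply(nat, 2, stats::quantile, 0.025),
      q97.5 = apply(nat, 2, stats::quantile, 0.975),
      stringsAsFactors = FALSE)
  }
  subjects <- do.call(rbind, rows)
  rownames(subjects) <- NULL
  group <- data.frame(parameter = fit$par_names,
                      mean = colMeans(post_means),
                      sd_between = apply(post_means, 2, stats::sd),
                      stringsAsFactors = FALSE)
  nphi <- fit$n_chains * fit$n_keep
  phim <- matrix(fit$samples_phi, nphi, 2 * d)
  hyper <- data.frame(parameter = c(paste0("loc.", fit$par_names),
                                    paste0("scale.", fit$par_names)),
                      mean = colMeans(phim), sd = apply(phim, 2, stats::sd),
                      stringsAsFactors = FALSE)
  list(subjects = subjects, group = group, hyper = hyper)
}

scale_percent <- function(nat, par_names, percent) {
  if (!percent) return(nat)
  pct <- par_names %in% c("tf", "gf")
  nat[, pct] <- nat[, pct, drop = FALSE] * 100
  nat
}

#' Across-subject group means of the subject posterior means
#'
#' The natural-scale group estimate a descriptive table would print: for
#' each parameter, the mean across participants of the subject-level
#' posterior means.
#'
#' @inheritParams posterior_summary
#' @return named numeric vector.
#' @export
group_posterior_means <- function(fit, percent = TRUE) {
  ps <- posterior_summary(fit, percent = percent, check_convergence = FALSE)
  stats::setNames(ps$group$mean, ps$group$parameter)
}

#' @export
print.ss_hfit <- function(x, ...) {
  cat(sprintf("Hierarchical %s-model fit (%s / %s): %d subjects\n",
              x$model, x$task, x$condition, length(x$subjects)))
  cat(sprintf("  %d chains x %d retained iterations (burn-in %d)\n",
              x$n_chains, x$n_keep, x$n_burn))
  cat(sprintf("  R-hat: max %.3f | ESS: min %.0f, median %.0f\n",
              max(x$rhat, na.rm = TRUE), min(x$ess, na.rm = TRUE),
              stats::median(x$ess, na.rm = TRUE)))
  invisible(x)
}

#' @rdname posterior_summary
#' @param object,x an `ss_hfit`.
#' @param ... unused.
#' @export
summary.ss_hfit <- function(object, percent = TRUE, ...) {
  ps <- posterior_summary(object, percent = percent, check_convergence = FALSE)
  out <- list(fit = object, summary = ps)
  class(out) <- "summary.ss_hfit"
  out
}

#' @export
print.summary.ss_hfit <- function(x, ...) {
  print(x$fit)
  cat("\nGroup means (across-subject average of posterior means):\n")
  g <- x$summary$group
  for (i in seq_len(nrow(g)))
    cat(sprintf("  %-10s %10.3f (between-subject SD %8.3f)\n",
                g$parameter[i], g$mean[i], g$sd_between[i]))
  invisible(x)
}

#' @export
coef.ss_hfit <- function(object, percent = FALSE, ...) {
  d <- length(object$par_names)
  S <- length(object$subjects)
  out <- matrix(NA_real_, S, d,
                dimnames = list(object$subjects, object$par_names))
  for (s in seq_len(S)) {
    nat <- link_to_nat(matrix(object$samples_theta[, , s, ],
                              object$n_chains * object$n_keep, d),
                       object$links)
    out[s, ] <- colMeans(scale_percent(nat, object$par_names, percent))
  }
  out
}

#' Trace plots for a hierarchical fit
#'
#' Plots the retained chains of the group-level location parameters (the
#' visual "flat fat hairy caterpillars" convergence check).
#'
#' @param x an `ss_hfit`.
#' @param pars parameters to plot (default: all group locations).
#' @param ... passed to [graphics::matplot()].
#' @export
plot.ss_hfit <- function(x, pars = x$par_names, ...) {
  d <- length(x$par_names)
  idx <- match(pars, x$par_names)
  old <- graphics::par(mfrow = c(ceiling(length(idx) / 2), 2),
                       mar = c(3, 4, 2, 1))
  on.exit(graphics::par(old))
  for (j in idx) {
    tr <- t(x$samples_phi[, , j])  # iterations x chains
    graphics::matplot(tr, type = "l", lty = 1, col = grDevices::hcl.colors(x$n_chains),
                      xlab = "iteration", ylab = "",
                      main = paste0("loc.", x$par_names[j]), ...)
  }
  invisible(x)
}

#' Posterior-predictive simulation from a hierarchical fit
#'
#' Simulates sessions from the across-subject mean of the subject posterior
#' means (race fits) or forward trials from the same point estimate (DDM
#' fits).
#'
#' @param object an `ss_hfit`.
#' @param nsim number of trials to simulate.
#' @param seed optional integer seed.
#' @param ssd stop-signal delay used for race-model stop trials.
#' @param ... unused.
#' @return a data.frame of simulated trials.
#' @export
simulate.ss_hfit <- function(object, nsim = 1000, seed = NULL, ssd = 250, ...) {
  g <- group_posterior_means(object, percent = FALSE)
  if (object$model == "race") {
    p <- race_params(go = exgauss_params(g["mu_go"], g["sigma_go"], g["tau_go"]),
                     stop = exgauss_params(g["mu_stop"], g["sigma_stop"], g["tau_stop"]),
                     tf = g["tf"], gf = g["gf"])
    simulate_race_trials(p, ssd = ssd, n = nsim, seed = seed)
  } else {
    simulate_ddm_trials(ddm_params(a = g["a"], v = g["v"], t0 = g["t0"],
                                   z = g["z"]), n = nsim, seed = seed)
  }
}
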