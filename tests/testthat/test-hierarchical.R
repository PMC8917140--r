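make_small_race_data <- function(n_subj = 3, n_trials = 150, seed = 50) {
  bp <- study_blueprint(n_participants = n_subj)
  stopsignal:::with_seed(seed, {
    recs <- lapply(seq_len(n_subj), function(p) {
      sp <- draw_subject_params(bp, "classical", "control")
      run_session(session_config("classical", "control", n_trials = n_trials),
                  sp$race, participant_id = sprintf("P%02d", p),
                  p_correct = sp$p_go)
    })
    do.call(rbind, recs)
  })
}

test_that("hierarchical race fits are reproducible under a fixed seed", {
  dat <- make_small_race_data()
  f1 <- fit_race(dat, n_chains = 9, n_keep = 15, n_burn = 25, seed = 7)
  f2 <- fit_race(dat, n_chains = 9, n_keep = 15, n_burn = 25, seed = 7)
  expect_identical(f1$samples_theta, f2$samples_theta)
  expect_identical(f1$samples_phi, f2$samples_phi)
})

test_that("fit objects expose samples, diagnostics and natural-scale summaries", {
  dat <- make_small_race_data()
  fit <- fit_race(dat, n_chains = 9, n_keep = 20, n_burn = 40, seed = 8)
  expect_s3_class(fit, "race_fit")
  expect_identical(dim(fit$samples_theta), c(9L, 20L, 3L, 8L))
  expect_true(all(is.finite(fit$rhat)))
  expect_true(all(fit$ess <= 9 * 20 + 1e-9))
  ps <- posterior_summary(fit, check_convergence = FALSE)
  expect_identical(nrow(ps$group), 8L)
  expect_true(all(ps$subjects$mean[ps$subjects$parameter == "mu_stop"] > 0))
  # tf/gf reported on the percent scale by default
  natural <- posterior_summary(fit, percent = FALSE, check_convergence = FALSE)
  tf_pct <- ps$group$mean[ps$group$parameter == "tf"]
  tf_nat <- natural$group$mean[natural$group$parameter == "tf"]
  expect_equal(tf_pct, 100 * tf_nat)
  cf <- coef(fit)
  expect_identical(dim(cf), c(3L, 8L))
  expect_output(print(fit), "Hierarchical race-model fit")
  expect_output(print(summary(fit)), "Group means")
  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off())
  expect_silent(plot(fit, pars = c("mu_stop", "tau_stop")))
})

test_that("summarising an unconverged fit requires an explicit override", {
  dat <- make_small_race_data(n_subj = 3, n_trials = 120, seed = 51)
  short <- fit_race(dat, n_chains = 9, n_keep = 10, n_burn = 3, seed = 9)
  expect_gt(max(short$rhat, na.rm = TRUE), 1.1)
  expect_error(posterior_summary(short), "R-hat")
  expect_silent(ps <- posterior_summary(short, check_convergence = FALSE))
  expect_identical(nrow(ps$group), 8L)
})

test_that("a single-subject fit degenerates gracefully", {
  dat <- make_small_race_data(n_subj = 1, n_trials = 200, seed = 52)
  fit <- fit_race(dat, n_chains = 9, n_keep = 15, n_burn = 30, seed = 10)
  expect_identical(length(fit$subjects), 1L)
  expect_identical(dim(coef(fit)), c(1L, 8L))
})

test_that("hierarchical DDM fits run and keep z near its generating value", {
  set.seed(60)
  recs <- lapply(1:3, function(p) {
    sim <- simulate_ddm_trials(ddm_params(a = 1.7, v = 3.8, t0 = 220, z = 0.5),
                               n = 150, dt_ms = 0.5)
    ok <- !sim$censored
    data.frame(participant_id = sprintf("P%02d", p), task = "classical",
               condition = "control", trial_index = seq_len(150) - 1L,
               trial_type = "go", stimulus = "circle", ssd_ms = NA_real_,
               response = ifelse(ok, ifelse(sim$boundary == "upper",
                                            "left", "right"), "none"),
               rt_ms = ifelse(ok, sim$rt_ms, NA_real_),
               correct = ifelse(ok, sim$boundary == "upper", NA),
               stringsAsFactors = FALSE)
  })
  fit <- fit_ddm(do.call(rbind, recs), n_chains = 9, n_keep = 20, n_burn = 60,
                 seed = 61)
  expect_s3_class(fit, "ddm_fit")
  g <- group_posterior_means(fit, percent = FALSE)
  expect_true(g["z"] > 0.3 && g["z"] < 0.7)
  expect_true(g["t0"] > 100 && g["t0"] < 350)
  sim <- simulate(fit, nsim = 50, seed = 1)
  expect_identical(nrow(sim), 50L)
})

test_that("fits reject multi-cell input", {
  a <- run_session(session_config("classical", "control"),
                   default_race_agent(), seed = 1)
  b <- run_session(session_config("classical", "canal"),
                   default_race_agent(), seed = 2)
  expect_error(fit_race(rbind(a, b), n_chains = 9, n_keep = 5, n_burn = 5),
               "one task x condition cell")
})

test_that("the full hierarchical move set targets the exact conjugate posterior", {
  # normal-normal hierarchy with known reference posterior: every move type
  # (Gibbs locations, scale updates, crossover sweeps, non-centred and joint
  # full-state moves) must leave the correct target invariant
  spec <- list(model = "toy", par_names = "m", links = "identity",
               loc_m0 = 0, loc_s0 = 3, scale_hn = 2,
               extra_blocks = list(), n_full = 2L, n_asis = 1L, n_joint = 2L,
               loglik = function(th, dat)
                 rowSums(matrix(stats::dnorm(rep(dat$y, each = nrow(th)),
                                             th[, 1], 1, log = TRUE), nrow(th))),
               data_prep = function(records) list(y = records$y),
               init = function(dat) c(m = mean(dat$y)))
  set.seed(3)
  S <- 8
  ths <- rnorm(S, 1.5, 0.8)
  subj <- lapply(seq_len(S), function(s) rnorm(20, ths[s], 1))
  recs <- do.call(rbind, lapply(seq_len(S), function(s)
    data.frame(participant_id = sprintf("S%02d", s), task = "classical",
               condition = "control", y = subj[[s]])))
  fit <- stopsignal:::hier_fit(recs, spec, n_chains = 24, n_keep = 400,
                               n_burn = 200, migration_prob = 0.05, seed = 5)
  locs <- as.vector(fit$samples_phi[, , 1])
  scs <- as.vector(fit$samples_phi[, , 2])
  # reference: plain Gibbs + MH sampler for the same model
  gibbs <- function(n = 12000) {
    m <- 0; sc <- 1
    th <- vapply(subj, mean, numeric(1))
    out <- matrix(NA_real_, n, 2)
    for (i in seq_len(n)) {
      for (s in seq_len(S)) {
        v <- 1 / (20 + 1 / sc^2)
        th[s] <- rnorm(1, v * (sum(subj[[s]]) + m / sc^2), sqrt(v))
      }
      v <- 1 / (S / sc^2 + 1 / 9)
      m <- rnorm(1, v * sum(th) / sc^2, sqrt(v))
      for (k in 1:5) {
        scp <- abs(sc + rnorm(1, 0, 0.2))
        la <- sum(dnorm(th, m, scp, log = TRUE)) + dnorm(scp, 0, 2, log = TRUE) -
          sum(dnorm(th, m, sc, log = TRUE)) - dnorm(sc, 0, 2, log = TRUE)
        if (log(runif(1)) < la) sc <- scp
      }
      out[i, ] <- c(m, sc)
    }
    out[-seq_len(2000), ]
  }
  set.seed(9)
  ref <- gibbs()
  expect_equal(mean(locs), mean(ref[, 1]), tolerance = 0.05)
  expect_equal(sd(locs), sd(ref[, 1]), tolerance = 0.15)
  expect_equal(mean(scs), mean(ref[, 2]), tolerance = 0.08)
})
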