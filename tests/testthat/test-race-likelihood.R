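test_that("signal-respond density and stop-success mass obey total probability", {
  grid <- list(default_race_agent(tf = 0.05, gf = 0.003),
               default_race_agent(tf = 0, gf = 0),
               race_params(go = exgauss_params(420, 80, 110),
                           stop = exgauss_params(150, 50, 60),
                           tf = 0.15, gf = 0.02))
  for (p in grid) for (ssd in c(100, 250, 400)) {
    sr_mass <- stats::integrate(function(rt)
      exp(loglik_signal_respond(rt, ssd, p)), 1e-9, p$max_rt,
      rel.tol = 1e-10)$value
    expect_equal(sr_mass + race_success_prob(ssd, p), 1, tolerance = 1e-6)
  }
})

test_that("mixture terms collapse as the failure probabilities degenerate", {
  p <- default_race_agent(tf = 0, gf = 0)
  expect_equal(loglik_go_response(446, p),
               dexgauss(446, 361, 63, 85, log = TRUE))
  p_tf1 <- default_race_agent(tf = 1, gf = 0.01)
  expect_equal(loglik_signal_respond(500, 250, p_tf1),
               log(1 - 0.01) + dexgauss(500, 361, 63, 85, log = TRUE))
  # before the stop signal can race, the stop survival term is ~1 (exactly 1
  # up to the negligible negative-latency mass the full-support stop
  # distribution carries)
  p2 <- default_race_agent(tf = 0.3, gf = 0)
  expect_equal(loglik_signal_respond(200, 250, p2),
               dexgauss(200, 361, 63, 85, log = TRUE), tolerance = 1e-5)
  # gf = 1: all go responses impossible
  expect_equal(loglik_go_response(446, default_race_agent(gf = 1)), -Inf)
})

test_that("omission mass combines go failures and the deadline tail", {
  p_wide <- race_params(go = table2_go(), stop = table2_stop(),
                        tf = 0, gf = 0.5, max_rt = 1e7)
  expect_equal(loglik_go_omission(p_wide), log(0.5), tolerance = 1e-9)
  p0 <- race_params(go = table2_go(), stop = table2_stop(),
                    tf = 0, gf = 0, max_rt = 1e7)
  expect_lt(loglik_go_omission(p0), log(1e-12))
  # finite deadline: omission tail equals 1 - F_go(max_rt) by the CDF oracle
  p1 <- default_race_agent(gf = 0)
  expect_equal(exp(loglik_go_omission(p1)),
               1 - stats::integrate(function(t) dexgauss(t, 361, 63, 85),
                                    -500, 1200, rel.tol = 1e-11)$value,
               tolerance = 1e-8)
})

test_that("stop-success probability has the right limits and monotonicity", {
  p <- default_race_agent(tf = 0, gf = 0)
  probs <- race_success_prob(c(0, 100, 250, 400, 800), p)
  expect_true(all(diff(probs) < 0))
  # instantaneous stop process at delay 0 always wins
  p_fast <- race_params(go = table2_go(),
                        stop = exgauss_params(0, 1e-3, 1e-3), tf = 0, gf = 0)
  expect_equal(race_success_prob(0, p_fast), 1, tolerance = 1e-3)
})

test_that("analytic probabilities match Monte-Carlo race frequencies", {
  p <- default_race_agent(tf = 0.05, gf = 0.003)
  n <- 2e5
  for (ssd in c(150, 300)) {
    mc <- simulate_race_trials(p, ssd = ssd, n = n, seed = 1000 + ssd)
    p_hat <- mean(mc$outcome == "inhibited")
    p_an <- race_success_prob(ssd, p)
    expect_lt(abs(p_hat - p_an), 3 * sqrt(p_an * (1 - p_an) / n))
  }
})

test_that("dataset log-likelihood sums per-trial terms", {
  p <- default_race_agent()
  expect_identical(dataset_loglik(toy_records(go_rt = 400)[0, ], p), 0)
  single_go <- toy_records(go_rt = 446)
  expect_equal(dataset_loglik(single_go, p), loglik_go_response(446, p))
  single_inh <- toy_records(go_rt = 400, inh_ssd = 250)
  expect_equal(dataset_loglik(single_inh, p),
               loglik_go_response(400, p) + loglik_successful_stop(250, p))
  mixed <- rbind(toy_records(go_rt = 400),
                 toy_records(go_rt = 410, participant_id = "P02"))
  expect_error(dataset_loglik(mixed, p), "single participant")
})

test_that("the generating parameters dominate 30% perturbations in likelihood", {
  p <- default_race_agent(tf = 0.05, gf = 0.01)
  wins <- 0
  n_rep <- 20
  for (r in seq_len(n_rep)) {
    rec <- run_session(session_config("classical", "control", n_trials = 300),
                       p, seed = 300 + r)
    p_pert <- race_params(go = exgauss_params(361 * 1.3, 63 * 1.3, 85 * 0.7),
                          stop = exgauss_params(109 * 0.7, 36 * 1.3, 34 * 1.3),
                          tf = 0.05, gf = 0.01)
    if (dataset_loglik(rec, p) >= dataset_loglik(rec, p_pert)) wins <- wins + 1
  }
  expect_gte(wins, n_rep - 1)
})

test_that("the likelihood is continuous in the parameters", {
  rec <- run_session(session_config("classical", "control"), default_race_agent(),
                     seed = 4)
  base <- default_race_agent(tf = 0.05, gf = 0.01)
  l0 <- dataset_loglik(rec, base)
  for (eps in c(1e-4, 1e-5)) {
    p_eps <- race_params(go = exgauss_params(361 + eps, 63, 85),
                         stop = exgauss_params(109, 36 + eps, 34),
                         tf = 0.05 + eps, gf = 0.01)
    expect_lt(abs(dataset_loglik(rec, p_eps) - l0), 1)
  }
})

test_that("the stop-side shape is near-unidentified at study-scale trial counts", {
  # the generating shape and a skew-traded alternative with matched mean and
  # SD are separated by only a fraction of a log-likelihood unit over a full
  # 12-subject dataset; this is why the hierarchical fit needs informative
  # shape priors
  bp <- study_blueprint(n_participants = 12)
  dat <- stopsignal:::with_seed(7, {
    recs <- list(); tr <- list()
    for (p in 1:12) {
      sp <- draw_subject_params(bp, "classical", "control")
      recs[[p]] <- run_session(session_config("classical", "control",
                                              n_trials = 500),
                               sp$race, participant_id = sprintf("S%02d", p),
                               p_correct = sp$p_go)
      tr[[p]] <- sp$truth
    }
    list(r = do.call(rbind, recs), t = do.call(rbind, tr))
  })
  ll_truth <- 0; ll_skew <- 0
  for (i in 1:12) {
    rd <- stopsignal:::race_data_prep(
      dat$r[dat$r$participant_id == sprintf("S%02d", i), ], 1200)
    tt <- dat$t[i, ]
    th_truth <- matrix(unlist(tt[c("mu_go", "sigma_go", "tau_go", "mu_stop",
                                   "sigma_stop", "tau_stop", "tf", "gf")]), 1)
    th_skew <- th_truth
    th_skew[4:7] <- c(99, 15.8, 48.4, 0.068)  # matched mean/SD, higher skew
    ll_truth <- ll_truth + stopsignal:::race_ll_mat(th_truth, rd)
    ll_skew <- ll_skew + stopsignal:::race_ll_mat(th_skew, rd)
  }
  expect_lt(abs(ll_skew - ll_truth), 5)
})
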