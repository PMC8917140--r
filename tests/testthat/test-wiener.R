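test_that("upper and lower densities coincide for an unbiased zero-drift process", {
  p0 <- ddm_params(a = 1.5, v = 0, t0 = 0, z = 0.5)
  t <- c(50, 120, 300, 800, 2000)
  expect_equal(wiener_fpt_density(t, p0, "upper"),
               wiener_fpt_density(t, p0, "lower"))
})

test_that("defective densities integrate to the closed-form absorption probabilities", {
  grid <- list(ddm_params(a = 1.78, v = 4, t0 = 224, z = 0.51),
               ddm_params(a = 1.0, v = 0.5, t0 = 0, z = 0.3),
               ddm_params(a = 1.3, v = -2, t0 = 100, z = 0.6))
  for (p in grid) {
    iu <- stats::integrate(function(t) wiener_fpt_density(t, p, "upper"),
                           1e-7, 60000, rel.tol = 1e-10)$value
    il <- stats::integrate(function(t) wiener_fpt_density(t, p, "lower"),
                           1e-7, 60000, rel.tol = 1e-10)$value
    expect_equal(iu, ddm_absorption_prob(p, "upper"), tolerance = 1e-6)
    expect_equal(il, ddm_absorption_prob(p, "lower"), tolerance = 1e-6)
    expect_equal(iu + il, 1, tolerance = 1e-6)
  }
  # v = 0 limit of the absorption probability is the relative start point
  expect_equal(ddm_absorption_prob(ddm_params(a = 2, v = 0, t0 = 0, z = 0.37)),
               0.37)
})

test_that("series truncation is stable across the small/large-time switch", {
  # same evaluations at a much tighter error budget must agree to ~1e-7
  p <- ddm_params(a = 1.5, v = 1.5, t0 = 0, z = 0.45)
  t <- seq(100, 3000, by = 100)  # spans the series switching region
  d7 <- wiener_fpt_density(t, p, "upper", eps = 1e-7)
  d12 <- wiener_fpt_density(t, p, "upper", eps = 1e-12)
  expect_lt(max(abs(d7 - d12)), 1e-7)
})

test_that("the Euler simulator reproduces density and absorption probability", {
  p <- ddm_params(a = 1.78, v = 4, t0 = 224, z = 0.51)
  n <- 2e4
  d <- simulate_ddm_trials(p, n = n, seed = 9)
  expect_true(all(d$rt_ms >= 224, na.rm = TRUE))
  p_up <- ddm_absorption_prob(p, "upper")
  expect_lt(abs(mean(d$boundary == "upper") - p_up),
            3 * sqrt(p_up * (1 - p_up) / n) + 2e-3)
  # binned decision-time frequencies against the integrated density
  dt <- d$rt_ms[d$boundary == "upper"] - p$t0
  breaks <- c(0, 150, 250, 350, 500, 700, 1000, Inf)
  emp <- as.vector(table(cut(dt, breaks))) / length(dt)
  thr <- vapply(seq_len(length(breaks) - 2), function(i)
    stats::integrate(function(t) wiener_fpt_density(t, p, "upper"),
                     breaks[i] + 1e-9, breaks[i + 1])$value, numeric(1))
  thr <- c(thr, p_up - sum(thr)) / p_up
  se <- sqrt(thr * (1 - thr) / length(dt))
  expect_true(all(abs(emp - thr) < 4 * se + 0.005))
})

test_that("go-trial likelihood honours gf mixtures and the t0 floor", {
  p <- ddm_params(a = 1.78, v = 4, t0 = 224, z = 0.51)
  expect_warning(out <- loglik_go_trial(TRUE, 200, p), "rt <= t0")
  expect_identical(out, -Inf)
  # responded trial: (1 - gf) times the boundary density
  expect_equal(loglik_go_trial(TRUE, 450, p, gf = 0.1),
               log(0.9) + wiener_fpt_density(450 - 224, p, "upper", log = TRUE))
  expect_equal(loglik_go_trial(FALSE, 450, p, gf = 0),
               wiener_fpt_density(450 - 224, p, "lower", log = TRUE))
  # omission with gf = 0 and an effectively infinite deadline is impossible
  expect_lt(loglik_go_trial(TRUE, NA, p, gf = 0, max_rt = 60000), log(1e-8))
  expect_equal(loglik_go_trial(TRUE, NA, p, gf = 0.3, max_rt = 60000),
               log(0.3), tolerance = 1e-6)
})

test_that("correct-response probability at the group generating values is near ceiling", {
  # the closed form gives ~0.999; observed accuracy in such tasks is lower
  # because omissions and contaminants also count against it
  p <- ddm_params(a = 1.78, v = 4.00, t0 = 224, z = 0.51)
  expect_gte(ddm_absorption_prob(p, "upper"), 0.99)
})

test_that("posterior-predictive summaries are self-consistent", {
  p0 <- ddm_params(a = 1.5, v = 0, t0 = 150, z = 0.5)
  s0 <- fit_ddm_summary(p0, n = 5000, dt_ms = 0.5, seed = 2)
  expect_equal(s0$p_correct, 0.5, tolerance = 0.025)
  # speed-accuracy tradeoff direction: wider boundaries mean slower responses
  pa <- fit_ddm_summary(ddm_params(a = 1.2, v = 2, t0 = 150, z = 0.5),
                        n = 4000, dt_ms = 0.5, seed = 3)
  pb <- fit_ddm_summary(ddm_params(a = 2.2, v = 2, t0 = 150, z = 0.5),
                        n = 4000, dt_ms = 0.5, seed = 3)
  expect_gt(pb$mean_rt_correct, pa$mean_rt_correct)
  expect_gt(pb$p_correct, pa$p_correct)
})

test_that("single-subject maximum likelihood recovers the generating DDM", {
  # median over replicates: a, v within 10%, t0 within 10 ms
  gen <- ddm_params(a = 1.78, v = 4.00, t0 = 224, z = 0.51)
  set.seed(77)
  est <- replicate(5, {
    sim <- simulate_ddm_trials(gen, n = 500)
    dat <- stopsignal:::ddm_data_prep(
      data.frame(participant_id = "S", task = "classical",
                 condition = "control", trial_index = seq_len(500) - 1L,
                 trial_type = "go", stimulus = "x", ssd_ms = NA_real_,
                 response = ifelse(sim$boundary == "upper", "left", "right"),
                 rt_ms = sim$rt_ms, correct = sim$boundary == "upper",
                 stringsAsFactors = FALSE), 1200, "accuracy")
    # z is held at its generating value: with accuracy at ceiling the free-z
    # likelihood is flat along the a(1-z) ridge and single-subject ML drifts
    # along it (the hierarchical fits resolve this through the prior)
    nll <- function(x) {
      th <- matrix(c(exp(x[1]), x[2], exp(x[3]), 0.51, 1e-4), 1)
      -stopsignal:::ddm_ll_mat(th, dat)
    }
    o <- stats::optim(c(log(1.6), 3.5, log(200)), nll,
                      control = list(maxit = 800, reltol = 1e-9))
    c(a = exp(o$par[1]), v = o$par[2], t0 = exp(o$par[3]))
  })
  med <- apply(est, 1, stats::median)
  expect_lt(abs(med["a"] - 1.78) / 1.78, 0.10)
  expect_lt(abs(med["v"] - 4.00) / 4.00, 0.10)
  expect_lt(abs(med["t0"] - 224), 10)
})

test_that("response coding maps right-hand responses to the upper boundary", {
  rec <- data.frame(participant_id = "S", task = "classical",
                    condition = "control", trial_index = 0:1,
                    trial_type = "go", stimulus = "x", ssd_ms = NA_real_,
                    response = c("right", "left"), rt_ms = c(450, 500),
                    correct = c(TRUE, TRUE), stringsAsFactors = FALSE)
  acc <- stopsignal:::ddm_data_prep(rec, 1200, "accuracy")
  resp <- stopsignal:::ddm_data_prep(rec, 1200, "response")
  expect_identical(acc$rt_upper, c(450, 500))  # both correct
  expect_identical(resp$rt_upper, 450)         # only the right-hand response
  expect_identical(resp$rt_lower, 500)
})
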