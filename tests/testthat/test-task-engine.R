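test_that("trial composition is exact for every seed", {
  for (seed in 1:15) {
    s <- generate_trial_sequence(100, 0.3, seed = seed)
    expect_identical(sum(s == "stop"), 30L)
    expect_identical(length(s), 100L)
  }
  expect_identical(sum(generate_trial_sequence(50, 0.3, seed = 3) == "stop"), 15L)
  expect_identical(generate_trial_sequence(10, 0, seed = 1), rep("go", 10))
  expect_error(generate_trial_sequence(100, 1 / 3, seed = 1), "not an integer")
})

test_that("sequences respect the pseudo-randomisation constraints", {
  for (seed in 1:15) {
    s <- generate_trial_sequence(100, 0.3, seed = seed)
    expect_identical(s[1:2], c("go", "go"))
    r <- rle(s)
    expect_lte(max(r$lengths[r$values == "stop"]), 3L)
  }
  # long sessions (rejection sampling would practically never succeed here)
  s <- generate_trial_sequence(10000, 0.3, seed = 1)
  expect_identical(sum(s == "stop"), 3000L)
  r <- rle(s)
  expect_lte(max(r$lengths[r$values == "stop"]), 3L)
  expect_identical(generate_trial_sequence(100, 0.3, seed = 9),
                   generate_trial_sequence(100, 0.3, seed = 9))
})

test_that("staircase tracks one-up one-down with clamping", {
  st <- staircase_state()
  expect_equal(staircase_update(st, "inhibited")$ssd, 275)
  expect_equal(staircase_update(st, "responded")$ssd, 125)
  at_floor <- staircase_state(ssd = 0)
  expect_equal(staircase_update(at_floor, "responded")$ssd, 0)
  at_ceil <- staircase_state(ssd = 1125)
  expect_equal(staircase_update(at_ceil, "inhibited")$ssd, 1125)
  expect_error(staircase_state(ssd = -5), "bounds")
})

test_that("tilt-angle schedule is balanced and seeded", {
  sch <- sensorial_stimulus_schedule(60, seed = 4)
  expect_equal(unname(table(sch)), rep(10L, 6), ignore_attr = TRUE)
  expect_setequal(sensorial_stimulus_schedule(6, seed = 1), c(-3, -2, -1, 1, 2, 3))
  expect_identical(sensorial_stimulus_schedule(0, seed = 1), numeric(0))
  expect_error(sensorial_stimulus_schedule(10, angle_set = numeric(0)), "nonempty")
  expect_identical(sensorial_stimulus_schedule(33, seed = 7),
                   sensorial_stimulus_schedule(33, seed = 7))
})

test_that("run_session is deterministic and respects record invariants", {
  agent <- default_race_agent()
  cfg <- session_config("classical", "control")
  a <- run_session(cfg, agent, seed = 5)
  b <- run_session(cfg, agent, seed = 5)
  expect_identical(a, b)
  expect_true(all(is.na(a$ssd_ms[a$trial_type == "go"])))
  expect_true(all(!is.na(a$ssd_ms[a$trial_type == "stop"])))
  expect_true(all(is.na(a$rt_ms[a$response == "none"])))
  rts <- a$rt_ms[!is.na(a$rt_ms)]
  expect_true(all(rts > 0 & rts <= cfg$max_rt))
})

test_that("a dominant stop process walks the SSD up in 75 ms steps", {
  # go RTs near 900 ms, stop latencies near 10 ms: every stop trial inhibits
  agent <- race_params(go = exgauss_params(900, 10, 10),
                       stop = exgauss_params(10, 1, 1), tf = 0, gf = 0)
  tr <- run_session(session_config("classical", "control"), agent, seed = 2)
  stop_rows <- tr[tr$trial_type == "stop", ]
  # while SSD + stop latency stays well below the go RT, every stop trial is
  # inhibited and the SSD climbs 75 ms per stop trial
  k <- 8
  expect_true(all(stop_rows$response[1:k] == "none"))
  expect_equal(stop_rows$ssd_ms[1:k], seq(200, by = 75, length.out = k))
})

test_that("sensorial sessions carry signed angle stimuli", {
  cfg <- session_config("sensorial", "canal")
  expect_identical(cfg$n_trials, 50L)
  tr <- run_session(cfg, default_race_agent(), seed = 3)
  expect_true(all(as.numeric(tr$stimulus) %in% c(-3, -2, -1, 1, 2, 3)))
  expect_error(session_config("classical", "control", angle_set = c(1, 2)),
               "sensorial")
})

test_that("a diffusion agent drives sessions with model-generated accuracy", {
  agent <- list(ddm = ddm_params(a = 1.78, v = 4, t0 = 224, z = 0.51),
                stop = exgauss_params(109, 36, 34), tf = 0.05, gf = 0.01)
  tr <- run_session(session_config("classical", "control", n_trials = 50),
                    agent, seed = 14)
  expect_identical(nrow(tr), 50L)
  resp <- tr[!is.na(tr$rt_ms), ]
  expect_true(all(resp$rt_ms > 224))
  expect_gt(mean(resp$correct), 0.8)  # v = 4 accuracy is near ceiling
  expect_identical(run_session(session_config("classical", "control",
                                              n_trials = 20), agent, seed = 3),
                   run_session(session_config("classical", "control",
                                              n_trials = 20), agent, seed = 3))
  expect_error(run_session(session_config("classical", "control"), list(a = 1)),
               "agent")
})
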