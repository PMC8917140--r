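test_that("paired t reproduces the hand computation on differences 1, 2, 3", {
  out <- paired_ttest(c(2, 3, 4), c(1, 1, 1))
  expect_equal(out$t, 2 * sqrt(3), tolerance = 1e-12)
  expect_identical(out$df, 2)
  same <- paired_ttest(c(1, 2, 3), c(1, 2, 3))
  expect_identical(same$t, 0)
  expect_identical(same$p, 1)
  flipped <- paired_ttest(c(1, 1, 1), c(2, 3, 4))
  expect_equal(flipped$t, -2 * sqrt(3))
  expect_error(paired_ttest(1:3, 1:2), "paired")
})

test_that("JZS Bayes factor matches an independent quadrature oracle", {
  # oracle: Cauchy-prior representation, BF10 =
  #   int dt(t; nu, ncp = delta sqrt(n)) Cauchy(delta; 0, r) ddelta / dt(t; nu)
  oracle <- function(t, n, r = 0.707) {
    nu <- n - 1
    num <- stats::integrate(function(delta)
      suppressWarnings(stats::dt(t, nu, ncp = delta * sqrt(n))) *
        stats::dcauchy(delta, 0, r),
      -Inf, Inf, rel.tol = 1e-12, abs.tol = 0)$value
    num / stats::dt(t, nu)
  }
  for (t in c(0, 1, 2.5, 5)) for (n in c(10, 38)) {
    expect_equal(stopsignal:::jzs_bf10(t, n), oracle(t, n),
                 tolerance = 1e-6, label = sprintf("t=%g n=%d", t, n))
  }
})

test_that("JZS Bayes factor favours the null at t = 0 and grows with |t|", {
  expect_lt(stopsignal:::jzs_bf10(0, 38), 1)
  bfs <- vapply(c(0, 0.5, 1, 2, 3, 5), stopsignal:::jzs_bf10, numeric(1), n = 38)
  expect_true(all(diff(bfs) > 0))
  expect_equal(stopsignal:::jzs_bf10(-2, 38), stopsignal:::jzs_bf10(2, 38),
               tolerance = 1e-9)
  # identical samples support the null for any n >= 3
  for (n in c(3, 10, 38)) {
    x <- rnorm(n)
    expect_lt(jzs_bf_paired(x, x)$bf10, 1)
  }
})

test_that("Holm adjustment reproduces the worked example and dominates Bonferroni", {
  expect_equal(holm_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(holm_adjust(0.02), 0.02)
  expect_equal(holm_adjust(rep(0.3, 4)), rep(min(4 * 0.3, 1), 4))
  set.seed(2)
  p <- runif(10)
  expect_true(all(holm_adjust(p) <= pmin(length(p) * p, 1) + 1e-12))
  expect_error(holm_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("repeated-measures ANOVA matches hand-computed sums of squares", {
  # 4 subjects x 3 levels worked example
  m <- rbind(c(8, 10, 12), c(6, 7, 11), c(9, 12, 13), c(5, 9, 10))
  grand <- mean(m)
  ss_level <- nrow(m) * sum((colMeans(m) - grand)^2)
  ss_subj <- ncol(m) * sum((rowMeans(m) - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_level - ss_subj
  F_hand <- (ss_level / 2) / (ss_err / 6)
  out <- rm_anova_oneway(m)
  expect_equal(out$F, F_hand, tolerance = 1e-10)
  expect_identical(c(out$df1, out$df2), c(2L, 6L))
  # invariances and degenerate inputs
  expect_equal(rm_anova_oneway(m + 100)$F, F_hand, tolerance = 1e-10)
  expect_identical(rm_anova_oneway(matrix(rep(1:4, 3), 4, 3))$F, 0)
  m_bad <- m; m_bad[2, 2] <- NA
  expect_error(rm_anova_oneway(m_bad), "complete")
})

test_that("log Bayes factors map onto the conventional evidence labels", {
  expect_identical(interpret_log_bf(0), "no evidence")
  expect_identical(interpret_log_bf(log(150)), "extreme evidence for H1")
  expect_identical(interpret_log_bf(log(5)), "moderate evidence for H1")
  expect_match(interpret_log_bf(-log(4)), "evidence for H0")
  expect_error(interpret_log_bf(Inf), "finite")
})

test_that("the BIC Bayes factor approximation points the right way", {
  set.seed(4)
  strong <- cbind(rnorm(20), rnorm(20) + 3)
  null <- cbind(rnorm(20), rnorm(20))
  expect_gt(bf_rm_anova_bic(strong)$log_bf10, 0)
  expect_lt(bf_rm_anova_bic(null)$log_bf10, 0)
})

test_that("contrasts_report pairs participants and applies Holm across contrasts", {
  set.seed(6)
  sm <- rbind(
    data.frame(participant_id = sprintf("P%02d", 1:20), condition = "control",
               ssrt = rnorm(20, 150, 20)),
    data.frame(participant_id = sprintf("P%02d", 1:20), condition = "canal",
               ssrt = rnorm(20, 190, 20)),
    data.frame(participant_id = sprintf("P%02d", 1:20), condition = "otolith",
               ssrt = rnorm(20, 152, 20)))
  rep <- contrasts_report(sm, "ssrt")
  expect_identical(nrow(rep), 2L)
  expect_identical(rep$n, c(20L, 20L))
  expect_true(all(rep$p_holm >= rep$p))
  expect_gt(rep$log_bf10[rep$contrast == "canal - control"], 0)
})
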