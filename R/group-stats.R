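#' Paired t test
#'
#' Classical paired t on the within-participant differences, returned as a
#' bare list for downstream tabulation.
#'
#' @param x,y equal-length paired samples (n >= 2).
#' @return list with `t`, `df`, `p`.
#' @examples
#' paired_ttest(c(2, 3, 4), c(1, 1, 1))  # differences 1,2,3 -> t = 2*sqrt(3)
#' @export
paired_ttest <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must be paired", call. = FALSE)
  if (length(x) < 2) stop("need n >= 2 pairs", call. = FALSE)
  if (stats::sd(x - y) == 0) {
    if (mean(x - y) != 0)
      stop("zero-variance nonzero differences: t undefined", call. = FALSE)
    return(list(t = 0, df = length(x) - 1, p = 1))
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}

#' Default-prior (JZS) Bayes factor for a paired t test
#'
#' Bayes factor BF10 comparing the alternative (standardised effect size with
#' a zero-centred Cauchy prior of scale `cauchy_scale`, default 0.707) to the
#' point null, computed by numerical integration of the Zellner-Siow marginal
#' likelihood ratio in its inverse-gamma mixture representation:
#' \deqn{BF_{10} = \frac{\int_0^\infty (1+Ng)^{-1/2}
#'   \big(1 + \frac{t^2}{(1+Ng)\nu}\big)^{-(\nu+1)/2} \pi(g)\,dg}
#'   {\big(1 + \frac{t^2}{\nu}\big)^{-(\nu+1)/2}}}
#' with \eqn{g \sim} InverseGamma(1/2, `cauchy_scale`^2/2), `N` pairs and
#' \eqn{\nu = N - 1} degrees of freedom. `log_bf10` is the natural
#' logarithm: negative values support the null, positive values the
#' alternative.
#'
#' @inheritParams paired_ttest
#' @param cauchy_scale Cauchy prior scale on the standardised effect
#'   (default 0.707, a "medium" effect-size prior).
#' @return list of class `"bayes_result"` with `t, df, p, bf10, log_bf10,
#'   label` (see [interpret_log_bf()]).
#' @examples
#' jzs_bf_paired(rnorm(20), rnorm(20))
#' @export
jzs_bf_paired <- function(x, y, cauchy_scale = 0.707) {
  tt <- paired_ttest(x, y)
  bf <- jzs_bf10(tt$t, n = length(x), rscale = cauchy_scale)
  out <- list(t = tt$t, df = tt$df, p = tt$p, bf10 = bf, log_bf10 = base::log(bf),
              label = interpret_log_bf(base::log(bf)))
  class(out) <- "bayes_result"
  out
}

# BF10 from a t statistic and sample size (one-sample / paired design).
jzs_bf10 <- function(t, n, rscale = 0.707) {
  nu <- n - 1
  log_null <- -(nu + 1) / 2 * log1p(t^2 / nu)
  # integrand over g on the log scale: likelihood x InverseGamma(1/2, r^2/2)
  log_ig <- function(g) 0.5 * base::log(rscale^2 / 2) - lgamma(0.5) -
    1.5 * base::log(g) - rscale^2 / (2 * g)
  f <- function(g) exp(-0.5 * log1p(n * g) -
                         (nu + 1) / 2 * log1p(t^2 / ((1 + n * g) * nu)) +
                         log_ig(g) - log_null)
  # substitute g = u / (1 - u) to integrate over (0, 1)
  h <- function(u) f(u / (1 - u)) / (1 - u)^2
  int <- stats::integrate(h, 0, 1, rel.tol = 1e-10, abs.tol = 0,
                          subdivisions = 500L)
  if (int$message != "OK")
    stop("JZS Bayes factor integration failed: ", int$message, call. = FALSE)
  int$value
}

#' @export
print.bayes_result <- function(x, ...) {
  cat(sprintf("t(%g) = %.3f, p = %.4g, BF10 = %.4g, log(BF10) = %.3f [%s]\n",
              x$df, x$t, x$p, x$bf10, x$log_bf10, x$label))
  invisible(x)
}

#' Holm step-down multiple-comparison adjustment
#'
#' @param pvals p values in \[0, 1\].
#' @return adjusted p values in the input order.
#' @examples
#' holm_adjust(c(0.01, 0.04, 0.03))  # 0.03 0.06 0.06
#' @export
holm_adjust <- function(pvals) {
  if (any(pvals < 0 | pvals > 1)) stop("p values must be in [0, 1]", call. = FALSE)
  stats::p.adjust(pvals, method = "holm")
}

#' One-way repeated-measures ANOVA
#'
#' F test for a single within-participant factor with subject blocking, on a
#' complete balanced subject x level matrix.
#'
#' @param data numeric matrix, rows = subjects, columns = factor levels.
#' @return list with `F`, `df1`, `df2`, `p`.
#' @examples
#' m <- matrix(rnorm(12), 4, 3)
#' rm_anova_oneway(m)
#' @export
rm_anova_oneway <- function(data) {
  data <- as.matrix(data)
  if (any(!is.finite(data)))
    stop("missing cells: repeated-measures ANOVA needs a complete matrix",
         call. = FALSE)
  if (nrow(data) < 2 || ncol(data) < 2)
    stop("need >= 2 subjects and >= 2 levels", call. = FALSE)
  df <- data.frame(y = as.vector(data),
                   subject = factor(rep(seq_len(nrow(data)), ncol(data))),
                   level = factor(rep(seq_len(ncol(data)), each = nrow(data))))
  fit <- stats::aov(y ~ level + Error(subject), data = df)
  tab <- summary(fit)[["Error: Within"]][[1]]
  rownames(tab) <- trimws(rownames(tab))
  Fv <- tab["level", "F value"]
  ss <- stats::setNames(tab[, "Sum Sq"], rownames(tab))
  if (ss["level"] <= 1e-10 * (sum(ss) + 1)) Fv <- 0  # identical columns
  list(F = Fv, df1 = as.integer(tab["level", "Df"]),
       df2 = as.integer(tab["Residuals", "Df"]),
       p = if (Fv == 0) 1 else tab["level", "Pr(>F)"])
}

#' BIC-approximate Bayes factor for a repeated-measures design
#'
#' A coarse Bayes factor for the within-participant factor, from the BIC
#' difference between linear models with and without the factor (both with
#' subject blocks): `BF10 ~= exp((BIC0 - BIC1) / 2)`. This is an
#' approximation to a default-prior Bayesian repeated-measures ANOVA, not a
#' reproduction of mixture-of-g-priors implementations; the conventional
#' r-scale settings of those implementations (fixed effects 0.5, random
#' effects 1, covariates 0.354) are recorded for documentation only.
#'
#' @inheritParams rm_anova_oneway
#' @return list with `log_bf10`, `bf10`, `approximation = "BIC"` and the
#'   recorded `r_scales`.
#' @export
bf_rm_anova_bic <- function(data) {
  data <- as.matrix(data)
  df <- data.frame(y = as.vector(data),
                   subject = factor(rep(seq_len(nrow(data)), ncol(data))),
                   level = factor(rep(seq_len(ncol(data)), each = nrow(data))))
  b1 <- stats::BIC(stats::lm(y ~ subject + level, data = df))
  b0 <- stats::BIC(stats::lm(y ~ subject, data = df))
  lbf <- (b0 - b1) / 2
  list(log_bf10 = lbf, bf10 = exp(lbf), approximation = "BIC",
       r_scales = c(fixed = 0.5, random = 1, covariates = 0.354))
}

#' Interpret a log Bayes factor
#'
#' Maps the natural-log Bayes factor onto the conventional evidential
#' categories (anecdotal / moderate / strong / very strong / extreme, with
#' cut points at BF = 3, 10, 30, 100 and their reciprocals). Negative values
#' support the null hypothesis, positive values the alternative.
#'
#' @param log_bf10 finite natural-log Bayes factor.
#' @return character label.
#' @examples
#' interpret_log_bf(0)
#' interpret_log_bf(log(50))
#' @export
interpret_log_bf <- function(log_bf10) {
  if (!is.finite(log_bf10)) stop("`log_bf10` must be finite", call. = FALSE)
  bf <- exp(log_bf10)
  if (bf == 1) return("no evidence")
  grade <- function(b) {
    c("anecdotal", "moderate", "strong", "very strong",
      "extreme")[findInterval(b, c(3, 10, 30, 100)) + 1]
  }
  if (bf > 1) paste(grade(bf), "evidence for H1")
  else paste(grade(1 / bf), "evidence for H0")
}

#' Condition/task contrasts over participant summaries
#'
#' Runs paired contrasts of a per-cell measure between two levels of a
#' within-participant factor, reporting the t test, Holm-adjusted p across
#' the requested contrasts, and the JZS Bayes factor with its label.
#'
#' @param summaries a data.frame with columns `participant_id`, the factor
#'   column, and the measure column (e.g. [subject_summaries()] output or a
#'   ground-truth parameter table).
#' @param measure name of the measure column.
#' @param factor_col name of the factor column (e.g. `"condition"`).
#' @param contrasts list of length-2 character vectors `c(level1, level2)`;
#'   each contrast tests level1 - level2.
#' @param cauchy_scale passed to [jzs_bf_paired()].
#' @return data.frame with one row per contrast: `measure, contrast, n, t,
#'   df, p, p_holm, bf10, log_bf10, label`.
#' @export
contrasts_report <- function(summaries, measure, factor_col = "condition",
                             contrasts = list(c("canal", "control"),
                                              c("otolith", "control")),
                             cauchy_scale = 0.707) {
  rows <- lapply(contrasts, function(ct) {
    a <- summaries[summaries[[factor_col]] == ct[1], ]
    b <- summaries[summaries[[factor_col]] == ct[2], ]
    ids <- intersect(a$participant_id, b$participant_id)
    x <- a[[measure]][match(ids, a$participant_id)]
    y <- b[[measure]][match(ids, b$participant_id)]
    keep <- is.finite(x) & is.finite(y)
    br <- jzs_bf_paired(x[keep], y[keep], cauchy_scale)
    data.frame(measure = measure, contrast = paste(ct, collapse = " - "),
               n = sum(keep), t = br$t, df = br$df, p = br$p,
               bf10 = br$bf10, log_bf10 = br$log_bf10, label = br$label,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_holm <- holm_adjust(out$p)
  out[, c("measure", "contrast", "n", "t", "df", "p", "p_holm",
          "bf10", "log_bf10", "label")]
}
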