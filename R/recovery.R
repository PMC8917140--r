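#' Parameter-recovery experiments against the generating group values
#'
#' `race_recovery()` simulates a cohort of subjects from the race model at a
#' cell's group generating values (subject parameters drawn from truncated
#' normals with the printed between-subject SDs), runs each subject through a
#' full adaptive-staircase session, fits the hierarchical race model and
#' compares the recovered group means (across-subject average of subject
#' posterior means) with the generating values. `ddm_recovery()` does the
#' same for the diffusion model on pure go-trial data.
#'
#' @param n_subjects number of synthetic subjects (default 12).
#' @param n_trials trials per subject for the race design (default 500,
#'   i.e. 350 go + 150 stop at the 30% stop fraction).
#' @param n_go go trials per subject for the DDM design (default 400).
#' @param task,condition the generating cell (default classical / control).
#' @param seed integer seed controlling both data generation and fitting.
#' @param n_chains,n_keep,n_burn sampler configuration (see [fit_race()]).
#' @param progress print sampler progress.
#' @return list with `fit`, `generating` (group means), `tolerance` (the
#'   printed between-subject SDs), `recovered` (group posterior means),
#'   `within` (logical per parameter: |recovered - generating| <= tolerance)
#'   and the simulated `trials` / `truth`.
#' @examples
#' \donttest{
#' rec <- race_recovery(n_subjects = 4, n_trials = 120, seed = 1,
#'                      n_chains = 12, n_keep = 30, n_burn = 60)
#' rec$within
#' }
#' @export
race_recovery <- function(n_subjects = 12, n_trials = 500,
                          task = "classical", condition = "control",
                          seed = NULL, n_chains = 33, n_keep = 120,
                          n_burn = 500, progress = FALSE) {
  bp <- study_blueprint(n_participants = n_subjects)
  cp <- bp$params[[paste(task, condition, sep = ".")]]
  dat <- with_seed(seed, {
    recs <- list(); truth <- list()
    ids <- sprintf("S%02d", seq_len(n_subjects))
    for (p in seq_along(ids)) {
      sp <- draw_subject_params(bp, task, condition)
      cfg <- session_config(task, condition, n_trials = n_trials)
      recs[[p]] <- run_session(cfg, sp$race, participant_id = ids[p],
                               p_correct = sp$p_go)
      truth[[p]] <- data.frame(participant_id = ids[p], t(sp$truth),
                               stringsAsFactors = FALSE)
    }
    list(trials = do.call(rbind, recs), truth = do.call(rbind, truth))
  })
  fit <- fit_race(dat$trials, n_chains = n_chains, n_keep = n_keep,
                  n_burn = n_burn, seed = if (is.null(seed)) NULL else seed + 1,
                  progress = progress)
  rec <- group_posterior_means(fit, percent = TRUE)
  generating <- c(mu_stop = unname(cp$mu_stop["mean"]),
                  sigma_stop = unname(cp$sigma_stop["mean"]),
                  tau_stop = unname(cp$tau_stop["mean"]),
                  tf = unname(cp$tf_pct["mean"]),
                  gf = unname(cp$gf_pct["mean"]))
  tolerance <- c(mu_stop = unname(cp$mu_stop["sd"]),
                 sigma_stop = unname(cp$sigma_stop["sd"]),
                 tau_stop = unname(cp$tau_stop["sd"]),
                 tf = unname(cp$tf_pct["sd"]),
                 gf = unname(cp$gf_pct["sd"]))
  recovered <- rec[names(generating)]
  list(fit = fit, generating = generating, tolerance = tolerance,
       recovered = recovered,
       within = abs(recovered - generating) <= tolerance,
       trials = dat$trials, truth = dat$truth)
}

#' @rdname race_recovery
#' @export
ddm_recovery <- function(n_subjects = 12, n_go = 400,
                         task = "classical", condition = "control",
                         seed = NULL, n_chains = 33, n_keep = 120,
                         n_burn = 500, progress = FALSE) {
  bp <- study_blueprint(n_participants = n_subjects)
  cp <- bp$params[[paste(task, condition, sep = ".")]]
  dat <- with_seed(seed, {
    recs <- list(); truth <- list()
    ids <- sprintf("S%02d", seq_len(n_subjects))
    for (p in seq_along(ids)) {
      sp <- draw_subject_params(bp, task, condition)
      gf <- sp$race$gf
      omit <- stats::runif(n_go) < gf
      sim <- simulate_ddm_trials(sp$ddm, n = n_go)
      responded <- !omit & !sim$censored & sim$rt_ms <= 1200
      correct <- sim$boundary == "upper"
      recs[[p]] <- data.frame(
        participant_id = ids[p], task = task, condition = condition,
        trial_index = seq_len(n_go) - 1L, trial_type = "go",
        stimulus = "circle", ssd_ms = NA_real_,
        response = ifelse(responded, ifelse(correct, "left", "right"), "none"),
        rt_ms = ifelse(responded, sim$rt_ms, NA_real_),
        correct = ifelse(responded, correct, NA),
        stringsAsFactors = FALSE)
      truth[[p]] <- data.frame(participant_id = ids[p], t(sp$truth),
                               stringsAsFactors = FALSE)
    }
    list(trials = do.call(rbind, recs), truth = do.call(rbind, truth))
  })
  fit <- fit_ddm(dat$trials, n_chains = n_chains, n_keep = n_keep,
                 n_burn = n_burn, seed = if (is.null(seed)) NULL else seed + 1,
                 progress = progress)
  rec <- group_posterior_means(fit, percent = FALSE)
  generating <- c(a = unname(cp$a["mean"]), v = unname(cp$nu["mean"]),
                  t0 = unname(cp$t0["mean"]), z = unname(cp$z["mean"]))
  tolerance <- c(a = unname(cp$a["sd"]), v = unname(cp$nu["sd"]),
                 t0 = unname(cp$t0["sd"]), z = unname(cp$z["sd"]))
  recovered <- rec[names(generating)]
  list(fit = fit, generating = generating, tolerance = tolerance,
       recovered = recovered,
       within = abs(recovered - generating) <= tolerance,
       trials = dat$trials, truth = dat$truth)
}
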