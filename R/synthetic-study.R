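# Cell-wise generating values for the synthetic study. Stop-side parameters
# and TF/GF come from the descriptive group table of the emulated design
# (mean and between-subject SD per task x condition cell); the go-side
# ex-Gaussian is calibrated from the printed RT_Tot and IIV by the moment
# identities tau_go = 0.8 IIV, sigma_go = 0.6 IIV (so SD(go RT) = IIV) and
# mu_go = RT_Tot - tau_go. Diffusion parameters are the printed a, v, t0, z.
cell_defaults <- function() {
  cells <- expand.grid(task = c("classical", "sensorial"),
                       condition = c("control", "otolith", "canal"),
                       stringsAsFactors = FALSE)
  v <- function(cl_co, cl_ot, cl_ca, se_co, se_ot, se_ca)
    list(classical.control = cl_co, classical.otolith = cl_ot,
         classical.canal = cl_ca, sensorial.control = se_co,
         sensorial.otolith = se_ot, sensorial.canal = se_ca)
  ms <- function(mean, sd) c(mean = mean, sd = sd)
  raw <- list(
    mu_stop   = v(ms(109, 11), ms(112, 8), ms(106, 9),
                  ms(126, 15), ms(105, 9), ms(89, 19)),
    sigma_stop = v(ms(36, 8), ms(26, 5), ms(71, 19),
                   ms(35, 7), ms(52, 9), ms(84, 17)),
    tau_stop  = v(ms(34, 11), ms(36, 13), ms(59, 20),
                  ms(42, 14), ms(64, 22), ms(90, 21)),
    tf_pct    = v(ms(5.13, 6.08), ms(2.70, 2.72), ms(1.91, 2.45),
                  ms(3.38, 3.70), ms(1.05, 0.53), ms(4.37, 2.29)),
    gf_pct    = v(ms(0.28, 0.64), ms(0.26, 0.86), ms(0.52, 1.11),
                  ms(1.17, 1.21), ms(0.63, 1.47), ms(1.16, 1.39)),
    p_go_pct  = v(ms(98, 2), ms(98, 4), ms(97, 3),
                  ms(91, 6), ms(90, 10), ms(91, 7)),
    rt_tot    = v(ms(446, 77), ms(442, 85), ms(461, 88),
                  ms(417, 93), ms(407, 107), ms(416, 112)),
    iiv       = v(ms(105, 22), ms(96, 24), ms(115, 50),
                  ms(138, 31), ms(138, 34), ms(153, 60)),
    a         = v(ms(1.78, 0.18), ms(1.73, 0.16), ms(1.74, 0.13),
                  ms(1.35, 0.21), ms(1.33, 0.24), ms(1.26, 0.15)),
    nu        = v(ms(4.00, 0.44), ms(4.20, 0.46), ms(3.91, 0.36),
                  ms(1.49, 1.44), ms(1.26, 1.40), ms(1.43, 1.23)),
    t0        = v(ms(224, 68), ms(238, 77), ms(239, 62),
                  ms(151, 78), ms(151, 95), ms(143, 85)),
    z         = v(ms(0.51, 0.05), ms(0.51, 0.06), ms(0.51, 0.06),
                  ms(0.52, 0.07), ms(0.50, 0.06), ms(0.51, 0.07)))
  out <- list()
  for (i in seq_len(nrow(cells))) {
    key <- paste(cells$task[i], cells$condition[i], sep = ".")
    cell <- lapply(raw, function(p) p[[key]])
    # derived go-side ex-Gaussian (means and between-subject SDs)
    cell$tau_go <- c(mean = unname(0.8 * cell$iiv["mean"]),
                     sd = unname(0.8 * cell$iiv["sd"]))
    cell$sigma_go <- c(mean = unname(0.6 * cell$iiv["mean"]),
                       sd = unname(0.6 * cell$iiv["sd"]))
    cell$mu_go <- c(mean = unname(cell$rt_tot["mean"] - cell$tau_go["mean"]),
                    sd = unname(cell$rt_tot["sd"]))
    out[[key]] <- cell
  }
  out
}

#' Blueprint of a synthetic stop-signal study
#'
#' Describes a full within-subject study: participants, the 2 task x 3
#' condition cells with their trial counts (100 control / 50 canal and
#' otolith, 70% go / 30% stop), and per-cell group-level generating means and
#' between-subject SDs for the race, accuracy and diffusion parameters. The
#' defaults encode the descriptive group table of the emulated vestibular
#' study, so the default blueprint embodies its condition effects (e.g. the
#' classical-task Canal sigma_stop mean of 71 ms against 36 ms in Control).
#' Printed between-subject SDs are used as the subject-draw SDs, an
#' acknowledged approximation (they also contain estimation error).
#'
#' @param n_participants number of participants (default 38).
#' @param seed integer seed stored in the blueprint and used by
#'   [generate_study()].
#' @param cells data.frame with `task`, `condition` rows to include
#'   (default: all six cells).
#' @param shared_subject_effect SD (as a fraction of each parameter's
#'   between-subject SD) of a subject-level random effect shared across
#'   cells; 0 (default) draws cells independently.
#' @return list of class `"study_blueprint"` with a `params` list mapping
#'   `"task.condition"` to per-parameter `c(mean, sd)` pairs.
#' @examples
#' bp <- study_blueprint(n_participants = 3, seed = 1)
#' bp$params[["classical.control"]]$sigma_stop
#' @export
study_blueprint <- function(n_participants = 38, seed = NULL, cells = NULL,
                            shared_subject_effect = 0) {
  if (n_participants < 1) stop("need at least one participant", call. = FALSE)
  if (is.null(cells))
    cells <- expand.grid(task = c("classical", "sensorial"),
                         condition = c("control", "otolith", "canal"),
                         stringsAsFactors = FALSE)
  structure(list(n_participants = as.integer(n_participants), cells = cells,
                 params = cell_defaults()[paste(cells$task, cells$condition,
                                                sep = ".")],
                 shared_subject_effect = shared_subject_effect,
                 seed = seed),
            class = "study_blueprint")
}

#' @export
print.study_blueprint <- function(x, ...) {
  cat(sprintf("Synthetic study blueprint: %d participants x %d cells\n",
              x$n_participants, nrow(x$cells)))
  invisible(x)
}

# Truncated-normal draws by inverse-CDF. Errors when the truncation removes
# >= 99% of the mass (a starved draw signals a mis-specified blueprint).
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) return(rep(mean, n))
  pl <- stats::pnorm(lower, mean, sd)
  pu <- stats::pnorm(upper, mean, sd)
  if (pu - pl < 0.01)
    stop("truncation removes >= 99% of the distribution's mass", call. = FALSE)
  stats::qnorm(pl + stats::runif(n) * (pu - pl), mean, sd)
}

#' Draw subject-level generating parameters for one cell
#'
#' Subject parameters are drawn from normals truncated to their valid
#' domains, located at the cell's group mean with the printed
#' between-subject SD as scale. Times and SDs truncate to positive,
#' probabilities to their unit ranges.
#'
#' @param blueprint a [study_blueprint()].
#' @param task,condition the cell.
#' @param offset optional named vector of per-parameter shifts (in SD-fraction
#'   units) implementing a shared subject random effect.
#' @return list with `race` ([race_params()]), `ddm` ([ddm_params()]),
#'   `p_go` (go accuracy used for race-agent choice) and `truth` (named
#'   vector of all generating values).
#' @export
draw_subject_params <- function(blueprint, task, condition, offset = NULL) {
  cp <- blueprint$params[[paste(task, condition, sep = ".")]]
  if (is.null(cp)) stop("cell not in blueprint", call. = FALSE)
  draw <- function(name, lower = -Inf, upper = Inf) {
    m <- unname(cp[[name]]["mean"])
    if (!is.null(offset) && name %in% names(offset))
      m <- m + unname(offset[name]) * unname(cp[[name]]["sd"])
    rtruncnorm(1, m, unname(cp[[name]]["sd"]), lower, upper)
  }
  mu_go <- draw("mu_go", lower = 1)
  sigma_go <- draw("sigma_go", lower = 1)
  tau_go <- draw("tau_go", lower = 1)
  mu_stop <- draw("mu_stop", lower = 1)
  sigma_stop <- draw("sigma_stop", lower = 1)
  tau_stop <- draw("tau_stop", lower = 1)
  tf <- draw("tf_pct", lower = 0, upper = 100) / 100
  gf <- draw("gf_pct", lower = 0, upper = 100) / 100
  p_go <- draw("p_go_pct", lower = 0, upper = 100) / 100
  a <- draw("a", lower = 0.05)
  nu <- draw("nu")
  t0 <- draw("t0", lower = 1)
  z <- draw("z", lower = 0.01, upper = 0.99)
  list(race = race_params(go = exgauss_params(mu_go, sigma_go, tau_go),
                          stop = exgauss_params(mu_stop, sigma_stop, tau_stop),
                          tf = tf, gf = gf),
       ddm = ddm_params(a = a, v = nu, t0 = t0, z = z),
       p_go = p_go,
       truth = c(mu_go = mu_go, sigma_go = sigma_go, tau_go = tau_go,
                 mu_stop = mu_stop, sigma_stop = sigma_stop,
                 tau_stop = tau_stop, tf = tf, gf = gf, p_go = p_go,
                 a = a, v = nu, t0 = t0, z = z))
}

#' Generate a complete synthetic study
#'
#' For every participant x cell, draws subject-level generating parameters
#' from the blueprint and simulates a full adaptive-staircase session with a
#' race agent (ex-Gaussian go RTs; response correctness Bernoulli at the
#' cell's go accuracy). Control cells have 100 trials, Canal and Otolith 50,
#' all with an exact 30% stop-trial fraction. Fully reproducible from the
#' blueprint seed.
#'
#' @param blueprint a [study_blueprint()].
#' @return list with `trials` (trial data.frame across all participants and
#'   cells), `truth` (one row of generating parameters per participant x
#'   cell) and `blueprint`.
#' @examples
#' study <- generate_study(study_blueprint(n_participants = 2, seed = 1))
#' nrow(study$truth)  # 2 participants x 6 cells
#' @export
generate_study <- function(blueprint) {
  stopifnot(inherits(blueprint, "study_blueprint"))
  with_seed(blueprint$seed, {
    trials <- list(); truth <- list()
    ids <- sprintf("P%02d", seq_len(blueprint$n_participants))
    for (p in seq_along(ids)) {
      shared <- NULL
      if (blueprint$shared_subject_effect > 0) {
        pn <- names(blueprint$params[[1]])
        shared <- stats::setNames(
          stats::rnorm(length(pn), 0, blueprint$shared_subject_effect), pn)
      }
      for (i in seq_len(nrow(blueprint$cells))) {
        task <- blueprint$cells$task[i]
        condition <- blueprint$cells$condition[i]
        sp <- draw_subject_params(blueprint, task, condition, offset = shared)
        cfg <- session_config(task, condition)
        rec <- run_session(cfg, sp$race, seed = NULL, participant_id = ids[p],
                           p_correct = sp$p_go)
        trials[[length(trials) + 1]] <- rec
        truth[[length(truth) + 1]] <- data.frame(
          participant_id = ids[p], task = task, condition = condition,
          t(sp$truth), stringsAsFactors = FALSE)
      }
    }
    list(trials = do.call(rbind, trials), truth = do.call(rbind, truth),
         blueprint = blueprint)
  })
}

#' Modify the generating means of a blueprint
#'
#' Builds variants of a blueprint: `null = TRUE` collapses every condition
#' onto its task's Control generating means (a no-effect blueprint for
#' specificity checks); `scale` multiplies every condition-minus-control mean
#' difference (2 doubles each effect); `set` overrides individual cell means
#' by name.
#'
#' @param blueprint a [study_blueprint()].
#' @param null collapse all conditions onto Control means.
#' @param scale multiplier applied to condition-minus-control mean
#'   differences (default 1).
#' @param set named numeric vector `"task.condition.parameter" = mean`
#'   overriding specific cell means; unknown names are an error.
#' @return the modified blueprint.
#' @examples
#' bp0 <- inject_effects(study_blueprint(seed = 1), null = TRUE)
#' bp2 <- inject_effects(study_blueprint(seed = 1), scale = 2)
#' @export
inject_effects <- function(blueprint, null = FALSE, scale = 1, set = NULL) {
  stopifnot(inherits(blueprint, "study_blueprint"))
  if (null || scale != 1) {
    for (key in names(blueprint$params)) {
      task <- strsplit(key, ".", fixed = TRUE)[[1]][1]
      ctrl <- blueprint$params[[paste0(task, ".control")]]
      if (is.null(ctrl))
        stop("blueprint lacks the control cell needed as reference", call. = FALSE)
      for (pn in names(blueprint$params[[key]])) {
        m0 <- ctrl[[pn]]["mean"]
        m <- blueprint$params[[key]][[pn]]["mean"]
        new_m <- if (null) m0 else m0 + scale * (m - m0)
        blueprint$params[[key]][[pn]]["mean"] <- new_m
      }
    }
  }
  if (!is.null(set)) {
    for (nm in names(set)) {
      parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
      if (length(parts) != 3 ||
          is.null(blueprint$params[[paste(parts[1], parts[2], sep = ".")]][[parts[3]]]))
        stop(sprintf("unknown effect target `%s`", nm), call. = FALSE)
      blueprint$params[[paste(parts[1], parts[2], sep = ".")]][[parts[3]]]["mean"] <- set[[nm]]
    }
  }
  blueprint
}

#' Ground-truth parameter draws for many subjects (no simulation)
#'
#' Draws subject-level generating parameters for every participant x cell of
#' a blueprint without simulating trials -- the cheap route to
#' direction-of-effect and specificity checks on the generating structure.
#'
#' @param blueprint a [study_blueprint()].
#' @param seed optional integer seed (defaults to the blueprint seed).
#' @return data.frame like the `truth` element of [generate_study()].
#' @export
draw_study_truth <- function(blueprint, seed = blueprint$seed) {
  with_seed(seed, {
    rows <- list()
    ids <- sprintf("P%02d", seq_len(blueprint$n_participants))
    for (p in seq_along(ids)) for (i in seq_len(nrow(blueprint$cells))) {
      task <- blueprint$cells$task[i]
      condition <- blueprint$cells$condition[i]
      sp <- draw_subject_params(blueprint, task, condition)
      rows[[length(rows) + 1]] <- data.frame(
        participant_id = ids[p], task = task, condition = condition,
        t(sp$truth), stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  })
}
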