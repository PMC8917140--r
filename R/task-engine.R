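#' Configure a stop-signal session
#'
#' A session is one participant x task x condition block of trials. The design
#' mirrors a centrifuge-based vestibular study: a classical (shape
#' discrimination) and a sensorial (line tilt discrimination relative to the
#' gravitational reference) stop-signal task, each run in a Control condition
#' (100 trials) and two rotation conditions, Canal and Otolith (50 trials each,
#' rotation time being limited), with 70% go and 30% stop trials throughout.
#'
#' @param task `"classical"` or `"sensorial"`.
#' @param condition `"control"`, `"canal"` or `"otolith"`.
#' @param n_trials number of trials; defaults to 100 for control and 50
#'   otherwise. `n_trials * p_stop` must be an integer: the trial composition
#'   is exact, not Bernoulli.
#' @param p_stop fraction of stop trials in (0, 1), default 0.3.
#' @param max_rt response deadline, ms (default 1200).
#' @param fixation_ms,iti_ms fixation and inter-trial intervals, ms (default
#'   250 each). Carried as metadata; they enter no likelihood.
#' @param angle_set signed tilt angles (degrees from the gravitational
#'   reference) used by the sensorial task; must be empty/NULL for the
#'   classical task.
#' @return a list of class `"session_config"`.
#' @examples
#' session_config("classical", "control")
#' session_config("sensorial", "canal")$n_trials  # 50
#' @export
session_config <- function(task = c("classical", "sensorial"),
                           condition = c("control", "canal", "otolith"),
                           n_trials = NULL, p_stop = 0.3, max_rt = 1200,
                           fixation_ms = 250, iti_ms = 250,
                           angle_set = NULL) {
  task <- match.arg(task)
  condition <- match.arg(condition)
  if (is.null(n_trials)) n_trials <- if (condition == "control") 100L else 50L
  if (n_trials <= 0) stop("`n_trials` must be positive", call. = FALSE)
  if (p_stop < 0 || p_stop >= 1) stop("`p_stop` must be in [0, 1)", call. = FALSE)
  n_stop <- n_trials * p_stop
  if (abs(n_stop - round(n_stop)) > 1e-9)
    stop(sprintf("n_trials * p_stop = %g is not an integer: exact trial composition impossible",
                 n_stop), call. = FALSE)
  if (task == "sensorial") {
    if (is.null(angle_set)) angle_set <- c(-3, -2, -1, 1, 2, 3)
    if (length(angle_set) == 0) stop("sensorial task needs a nonempty `angle_set`", call. = FALSE)
  } else if (!is.null(angle_set) && length(angle_set) > 0) {
    stop("`angle_set` is only meaningful for the sensorial task", call. = FALSE)
  }
  structure(list(task = task, condition = condition,
                 n_trials = as.integer(n_trials), p_stop = p_stop,
                 max_rt = max_rt, fixation_ms = fixation_ms, iti_ms = iti_ms,
                 angle_set = angle_set),
            class = "session_config")
}

#' Generate a pseudo-randomised go/stop trial sequence
#'
#' The composition is exact: `n_trials * p_stop` stop trials, the rest go.
#' The shuffle is constrained so that the first two trials are go trials and
#' no more than three stop trials occur in a row, keeping the sequence
#' unpredictable without degenerate runs.
#'
#' @param n_trials total number of trials.
#' @param p_stop stop-trial fraction; `n_trials * p_stop` must be an integer.
#' @param seed integer seed; the sequence is deterministic given the seed.
#' @return character vector of `"go"` / `"stop"` of length `n_trials`.
#' @examples
#' table(generate_trial_sequence(100, 0.3, seed = 1))
#' @export
generate_trial_sequence <- function(n_trials, p_stop, seed = NULL) {
  n_stop <- n_trials * p_stop
  if (abs(n_stop - round(n_stop)) > 1e-9)
    stop(sprintf("n_trials * p_stop = %g is not an integer: exact trial composition impossible",
                 n_stop), call. = FALSE)
  n_stop <- as.integer(round(n_stop))
  base_seq <- rep(c("stop", "go"), c(n_stop, n_trials - n_stop))
  if (n_stop == 0L || n_stop == n_trials) return(base_seq)
  with_seed(seed, {
    s <- sample(base_seq)
    # local repair: swap offending stop trials with random go positions until
    # the constraints hold (first two trials go; no run of > 3 stops)
    for (attempt in seq_len(10000L)) {
      bad <- violating_positions(s)
      if (length(bad) == 0) return(s)
      go_pos <- which(s == "go")
      tgt <- go_pos[sample.int(length(go_pos), 1L)]
      src <- bad[sample.int(length(bad), 1L)]
      s[c(src, tgt)] <- s[c(tgt, src)]
    }
    stop("trial-sequence constraints unsatisfiable for this composition",
         call. = FALSE)
  })
}

violating_positions <- function(s) {
  bad <- integer(0)
  if (length(s) >= 1 && s[1] == "stop") bad <- c(bad, 1L)
  if (length(s) >= 2 && s[2] == "stop") bad <- c(bad, 2L)
  r <- rle(s)
  ends <- cumsum(r$lengths)
  long <- which(r$values == "stop" & r$lengths > 3L)
  for (i in long)
    bad <- c(bad, (ends[i] - r$lengths[i] + 4L):ends[i])
  unique(bad)
}

sequence_admissible <- function(s) {
  if (length(s) >= 1 && s[1] == "stop") return(FALSE)
  if (length(s) >= 2 && s[2] == "stop") return(FALSE)
  r <- rle(s)
  !any(r$values == "stop" & r$lengths > 3L)
}

#' The one-up one-down SSD staircase
#'
#' The stop-signal delay (SSD) starts at 200 ms and moves in 75 ms steps:
#' up after a successfully inhibited stop trial, down after a failed one.
#' This tracks the delay at which inhibition succeeds about 50% of the time.
#' The SSD is clamped to `[lower_bound, upper_bound]`; delays below zero or
#' beyond the response deadline are physically meaningless.
#'
#' @param ssd current stop-signal delay, ms.
#' @param step staircase step, ms (default 75).
#' @param initial initial SSD, ms (default 200).
#' @param lower_bound,upper_bound clamp bounds, ms.
#' @param state a `staircase_state`.
#' @param outcome `"inhibited"` (no response on the stop trial) or
#'   `"responded"`.
#' @return `staircase_state()` a state list; `staircase_update()` the updated
#'   state.
#' @examples
#' st <- staircase_state()
#' staircase_update(st, "inhibited")$ssd   # 275
#' staircase_update(st, "responded")$ssd   # 125
#' @export
staircase_state <- function(ssd = 200, step = 75, initial = 200,
                            lower_bound = 0, upper_bound = 1200 - step) {
  if (lower_bound > upper_bound) stop("staircase bounds inverted", call. = FALSE)
  if (ssd < lower_bound || ssd > upper_bound)
    stop("`ssd` outside staircase bounds", call. = FALSE)
  structure(list(ssd = ssd, step = step, initial = initial,
                 lower_bound = lower_bound, upper_bound = upper_bound),
            class = "staircase_state")
}

#' @rdname staircase_state
#' @export
staircase_update <- function(state, outcome = c("inhibited", "responded")) {
  outcome <- match.arg(outcome)
  delta <- if (outcome == "inhibited") state$step else -state$step
  state$ssd <- min(max(state$ssd + delta, state$lower_bound), state$upper_bound)
  state
}

#' Balanced tilt-angle schedule for the sensorial task
#'
#' Assigns signed tilt angles (degrees from the gravitational reference) to
#' trials, balanced across the angle set up to the remainder, and shuffled
#' deterministically by seed.
#'
#' @param n_trials number of trials to schedule.
#' @param angle_set signed angles to balance over (default \eqn{\pm 1, \pm 2,
#'   \pm 3} degrees).
#' @param seed integer seed.
#' @return numeric vector of length `n_trials`.
#' @examples
#' table(sensorial_stimulus_schedule(60, seed = 1))  # 10 of each
#' @export
sensorial_stimulus_schedule <- function(n_trials,
                                        angle_set = c(-3, -2, -1, 1, 2, 3),
                                        seed = NULL) {
  if (length(angle_set) == 0) stop("`angle_set` must be nonempty", call. = FALSE)
  if (n_trials == 0) return(numeric(0))
  k <- length(angle_set)
  base <- rep(angle_set, n_trials %/% k)
  with_seed(seed, {
    extra <- if (n_trials %% k > 0) sample(angle_set, n_trials %% k) else numeric(0)
    sample(c(base, extra))
  })
}

#' Simulate a full stop-signal session
#'
#' Runs a generative agent through a configured session: the trial sequence is
#' drawn with [generate_trial_sequence()], stop-signal delays follow the
#' one-up one-down staircase applied to the realised stop-trial outcomes, and
#' each trial is simulated from the agent.
#'
#' The agent is either a [race_params()] object (ex-Gaussian go RTs racing an
#' ex-Gaussian stop process, with trigger and go failures) or a list
#' `list(ddm = ddm_params(...), stop = exgauss_params(...), tf =, gf =)` in
#' which go RTs and response sides come from the diffusion model. For a race
#' agent, which models RT but not choice, response correctness is drawn as
#' Bernoulli(`p_correct`); sides follow the stimulus-response mapping
#' (classical: circle = left, square = right; sensorial: tilt sign).
#'
#' @param config a [session_config()].
#' @param agent generative agent, see Details.
#' @param seed integer seed; identical (config, agent, seed) give identical
#'   records.
#' @param participant_id identifier recorded on every trial.
#' @param p_correct probability that a responded go/stop-respond trial is
#'   correct (race agents only; the DDM agent produces its own accuracy).
#' @param staircase a [staircase_state()] to start from; defaults to a fresh
#'   200 ms / 75 ms staircase, i.e. the SSD resets at each session.
#' @return a data.frame of trial records with columns `participant_id, task,
#'   condition, trial_index, trial_type, stimulus, ssd_ms, response, rt_ms,
#'   correct`. `ssd_ms` is `NA` on go trials; `rt_ms` and `correct` are `NA`
#'   when no response was emitted.
#' @examples
#' agent <- race_params(go = exgauss_params(361, 63, 85),
#'                      stop = exgauss_params(109, 36, 34), tf = 0.05)
#' trials <- run_session(session_config("classical", "control"), agent, seed = 1)
#' table(trials$trial_type)
#' @export
run_session <- function(config, agent, seed = NULL, participant_id = "S1",
                        p_correct = 1, staircase = NULL) {
  stopifnot(inherits(config, "session_config"))
  agent <- normalize_agent(agent, config$max_rt)
  if (is.null(staircase))
    staircase <- staircase_state(upper_bound = config$max_rt - 75)
  with_seed(seed, {
    n <- config$n_trials
    types <- generate_trial_sequence(n, config$p_stop, seed = NULL)
    stimulus <- if (config$task == "sensorial") {
      as.character(sensorial_stimulus_schedule(n, config$angle_set, seed = NULL))
    } else {
      sample(c("circle", "square"), n, replace = TRUE)
    }
    ssd_ms <- rep(NA_real_, n)
    response <- character(n)
    rt_ms <- rep(NA_real_, n)
    correct <- rep(NA, n)
    for (i in seq_len(n)) {
      is_stop <- types[i] == "stop"
      ssd <- if (is_stop) staircase$ssd else NA_real_
      out <- simulate_agent_trial(agent, ssd, config$max_rt)
      if (is_stop) {
        ssd_ms[i] <- ssd
        staircase <- staircase_update(
          staircase, if (out$responded) "responded" else "inhibited")
      }
      if (out$responded) {
        rt_ms[i] <- out$rt
        ok <- if (is.na(out$correct)) stats::runif(1) < p_correct else out$correct
        correct[i] <- ok
        correct_side <- stimulus_correct_side(config$task, stimulus[i])
        response[i] <- if (ok) correct_side else setdiff(c("left", "right"), correct_side)
      } else {
        response[i] <- "none"
      }
    }
    data.frame(participant_id = participant_id, task = config$task,
               condition = config$condition, trial_index = seq_len(n) - 1L,
               trial_type = types, stimulus = stimulus, ssd_ms = ssd_ms,
               response = response, rt_ms = rt_ms, correct = correct,
               stringsAsFactors = FALSE)
  })
}

stimulus_correct_side <- function(task, stimulus) {
  if (task == "sensorial") {
    if (as.numeric(stimulus) < 0) "left" else "right"
  } else {
    if (stimulus == "circle") "left" else "right"
  }
}

normalize_agent <- function(agent, max_rt) {
  if (inherits(agent, "race_params")) {
    list(kind = "race",
         params = race_params(agent$go, agent$stop, agent$tf, agent$gf, max_rt))
  } else if (is.list(agent) && inherits(agent$ddm, "ddm_params")) {
    stopifnot(inherits(agent$stop, "exgauss_params"))
    list(kind = "ddm", ddm = agent$ddm, stop = agent$stop,
         tf = agent$tf %||% 0, gf = agent$gf %||% 0, max_rt = max_rt)
  } else {
    stop("`agent` must be race_params() or list(ddm =, stop =, tf =, gf =)",
         call. = FALSE)
  }
}

# One trial from the agent. ssd = NA means a go trial. Returns
# list(responded, rt, correct); correct is NA when the agent does not model
# choice (race agent).
simulate_agent_trial <- function(agent, ssd, max_rt) {
  if (agent$kind == "race") {
    p <- agent$params
    out <- simulate_race_trials(p, ssd = if (is.na(ssd)) 0 else ssd, n = 1,
                                go_only = is.na(ssd))
    list(responded = out$outcome == "signal_respond" || out$outcome == "go_response",
         rt = out$rt, correct = NA)
  } else {
    if (stats::runif(1) < agent$gf) return(list(responded = FALSE, rt = NA_real_, correct = NA))
    d <- simulate_ddm_trials(agent$ddm, n = 1)
    go_rt <- d$rt_ms
    go_ok <- !d$censored && go_rt <= max_rt
    if (!is.na(ssd)) {
      stopped <- FALSE
      if (stats::runif(1) >= agent$tf) {
        ssrt <- rexgauss(1, agent$stop$mu, agent$stop$sigma, agent$stop$tau)
        stopped <- !(go_ok && go_rt < ssd + ssrt)
      } else stopped <- !go_ok
      if (stopped) return(list(responded = FALSE, rt = NA_real_, correct = NA))
    } else if (!go_ok) {
      return(list(responded = FALSE, rt = NA_real_, correct = NA))
    }
    list(responded = TRUE, rt = go_rt, correct = d$boundary == "upper")
  }
}
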