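#' Simulate stop-signal race trials
#'
#' Draws trial outcomes from the independent horse-race model with trigger and
#' go failures. On each trial the go process is omitted with probability `gf`;
#' otherwise a go RT is drawn from the go ex-Gaussian. On a stop trial the
#' stop process fails to launch with probability `tf` (a trigger failure), in
#' which case the response is emitted whenever the go RT lands in
#' `(0, max_rt]`; otherwise a stop latency (SSRT) is drawn from the stop
#' ex-Gaussian and the response is emitted only if the go RT beats
#' `ssd + SSRT` and lands in `(0, max_rt]`. Any stop trial without an emitted
#' response counts as inhibited: an omitted go process is observationally
#' indistinguishable from a won race.
#'
#' @param params a [race_params()].
#' @param ssd stop-signal delay in ms (scalar, ignored when `go_only`).
#' @param n number of trials.
#' @param seed optional integer seed.
#' @param go_only simulate go trials (no stop process).
#' @return data.frame with columns `outcome` (`"go_response"`/`"go_omission"`
#'   for go trials; `"signal_respond"`/`"inhibited"`/`"go_omission"` never
#'   occurs on stop trials -- no-response stop trials are all `"inhibited"`)
#'   and `rt` (ms, `NA` when no response).
#' @examples
#' p <- race_params(go = exgauss_params(361, 63, 85),
#'                  stop = exgauss_params(109, 36, 34), tf = 0.05)
#' table(simulate_race_trials(p, ssd = 250, n = 1000, seed = 1)$outcome)
#' @export
simulate_race_trials <- function(params, ssd = 0, n = 1, seed = NULL,
                                 go_only = FALSE) {
  stopifnot(inherits(params, "race_params"))
  if (ssd < 0) stop("`ssd` must be >= 0", call. = FALSE)
  if (n == 0)
    return(data.frame(outcome = character(0), rt = numeric(0)))
  with_seed(seed, {
    go_runs <- stats::runif(n) >= params$gf
    go_rt <- rexgauss(n, params$go$mu, params$go$sigma, params$go$tau)
    in_window <- go_runs & go_rt > 0 & go_rt <= params$max_rt
    if (go_only) {
      outcome <- ifelse(in_window, "go_response", "go_omission")
      rt <- ifelse(in_window, go_rt, NA_real_)
    } else {
      triggered <- stats::runif(n) >= params$tf
      ssrt <- rexgauss(n, params$stop$mu, params$stop$sigma, params$stop$tau)
      beats_stop <- !triggered | (go_rt < ssd + ssrt)
      respond <- in_window & beats_stop
      outcome <- ifelse(respond, "signal_respond", "inhibited")
      rt <- ifelse(respond, go_rt, NA_real_)
    }
    data.frame(outcome = outcome, rt = rt, stringsAsFactors = FALSE)
  })
}

#' Simulate diffusion-model trials by Euler-Maruyama integration
#'
#' Evidence starts at `z * a` and accumulates with drift `v` and diffusion
#' noise `s` (per-second units) until it is absorbed at `a` (upper boundary,
#' the correct response under accuracy coding) or 0 (lower). The reported RT
#' is the first-passage time plus the non-decision time `t0`. Paths that have
#' not been absorbed after `max_decision_ms` of decision time are flagged
#' censored.
#'
#' @param params a [ddm_params()].
#' @param n number of trials.
#' @param dt_ms Euler step in ms (default 0.1; discretisation bias at this
#'   step is far below the Monte-Carlo noise of any realistic sample size).
#' @param max_decision_ms hard cap on decision time (default 20000).
#' @param seed optional integer seed.
#' @return data.frame with columns `boundary` (`"upper"`/`"lower"`, `NA` when
#'   censored), `rt_ms` (`t0` + first-passage time, `NA` when censored) and
#'   `censored`.
#' @examples
#' d <- simulate_ddm_trials(ddm_params(a = 1.78, v = 4, t0 = 224, z = 0.51),
#'                          n = 200, seed = 1)
#' mean(d$boundary == "upper")
#' @export
simulate_ddm_trials <- function(params, n = 1, dt_ms = 0.1,
                                max_decision_ms = 20000, seed = NULL) {
  stopifnot(inherits(params, "ddm_params"))
  if (n == 0)
    return(data.frame(boundary = character(0), rt_ms = numeric(0),
                      censored = logical(0)))
  with_seed(seed, {
    dt_s <- dt_ms / 1000
    drift <- params$v * dt_s
    noise <- params$s * sqrt(dt_s)
    a <- params$a
    max_steps <- ceiling(max_decision_ms / dt_ms)
    x <- rep(params$z * a, n)
    steps <- rep(NA_integer_, n)
    boundary <- rep(NA_character_, n)
    active <- seq_len(n)
    step <- 0L
    while (length(active) > 0 && step < max_steps) {
      step <- step + 1L
      x[active] <- x[active] + drift + noise * stats::rnorm(length(active))
      xa <- x[active]
      hit_up <- xa >= a
      hit_lo <- xa <= 0
      finished <- hit_up | hit_lo
      if (any(finished)) {
        idx <- active[finished]
        steps[idx] <- step
        boundary[idx] <- ifelse(hit_up[finished], "upper", "lower")
        active <- active[!finished]
      }
    }
    censored <- is.na(boundary)
    rt_ms <- params$t0 + steps * dt_ms
    rt_ms[censored] <- NA_real_
    data.frame(boundary = boundary, rt_ms = rt_ms, censored = censored,
               stringsAsFactors = FALSE)
  })
}
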