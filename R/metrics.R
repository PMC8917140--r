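#' Inhibition accuracy
#'
#' Fraction of stop trials on which the response was successfully withheld
#' (no response emitted).
#'
#' @param records trial data.frame (one participant cell or any subset with
#'   stop trials).
#' @return fraction in \[0, 1\].
#' @export
p_inhib <- function(records) {
  st <- records[records$trial_type == "stop", ]
  if (nrow(st) == 0) stop("no stop trials in `records`", call. = FALSE)
  mean(st$response == "none")
}

#' Quantile-method SSRT estimate
#'
#' The standard single-number estimate of the stop-signal reaction time: all
#' RTs on correct go trials are sorted ascending, the RT at the quantile equal
#' to the proportion of failed inhibition (1 - P_inhib) is selected by
#' nearest rank (the `ceil(q n)`-th order statistic, no interpolation), and
#' the mean of all realised stop-signal delays is subtracted. The method does
#' not require inhibition to sit exactly at 50% and the result may be
#' negative (negative estimates feed the exclusion rules, see
#' [exclusion_filter()]).
#'
#' @param records trial data.frame for one participant cell, with at least
#'   one correct responded go trial and one stop trial.
#' @param replace_omissions if `TRUE`, omitted go trials enter the sorted RT
#'   list with RT = `max_rt` (the omission-replacement variant of the
#'   integration method). Off by default: the quantile list is restricted to
#'   correct go trials.
#' @param max_rt deadline used for `replace_omissions`.
#' @return SSRT estimate in ms.
#' @examples
#' # five correct go RTs, P_inhib = 0.6, mean SSD = 250 -> 450 - 250 = 200
#' @export
ssrt_quantile <- function(records, replace_omissions = FALSE, max_rt = 1200) {
  st <- records[records$trial_type == "stop", ]
  if (nrow(st) == 0) stop("no stop trials in `records`", call. = FALSE)
  go <- records[records$trial_type == "go", ]
  rts <- go$rt_ms[go$response != "none" & !is.na(go$rt_ms) &
                    !is.na(go$correct) & go$correct]
  if (replace_omissions)
    rts <- c(rts, rep(max_rt, sum(go$response == "none")))
  if (length(rts) == 0) stop("no correct go RTs in `records`", call. = FALSE)
  q <- 1 - p_inhib(records)
  rts <- sort(rts)
  idx <- max(1L, ceiling(q * length(rts)))
  rts[idx] - mean(st$ssd_ms)
}

#' Go-task RT and accuracy summaries
#'
#' Means over all responded go trials (`rt_tot`), correct responses only
#' (`rt_correct`) and errors only (`rt_error`); the within-participant SD of
#' responded-go RTs (`iiv_rt`); go accuracy `p_go` (correct responded go
#' trials over responded go trials -- omissions are counted separately); and
#' the go-failure percentage `gf_pct` (omitted go trials over all go trials,
#' x100). Undefined sub-means (e.g. no error trials) are `NA`, never 0.
#'
#' @param records trial data.frame with go trials.
#' @return named list with `rt_tot, rt_correct, rt_error, iiv_rt, p_go,
#'   gf_pct`.
#' @export
rt_summaries <- function(records) {
  go <- records[records$trial_type == "go", ]
  if (nrow(go) == 0) stop("no go trials in `records`", call. = FALSE)
  resp <- go[go$response != "none" & !is.na(go$rt_ms), ]
  corr <- resp[!is.na(resp$correct) & resp$correct, ]
  err <- resp[!is.na(resp$correct) & !resp$correct, ]
  list(rt_tot = if (nrow(resp)) mean(resp$rt_ms) else NA_real_,
       rt_correct = if (nrow(corr)) mean(corr$rt_ms) else NA_real_,
       rt_error = if (nrow(err)) mean(err$rt_ms) else NA_real_,
       iiv_rt = if (nrow(resp) > 1) stats::sd(resp$rt_ms) else NA_real_,
       p_go = if (nrow(resp)) nrow(corr) / nrow(resp) else NA_real_,
       gf_pct = 100 * sum(go$response == "none") / nrow(go))
}

#' Per-cell participant summaries
#'
#' Computes the standard behavioural metrics for every participant x task x
#' condition cell in a trial dataset: inhibition accuracy, quantile-method
#' SSRT, mean SSD, go accuracy, RT means, intra-individual RT variability and
#' go-failure percentage.
#'
#' @param records trial data.frame (any number of participants/cells).
#' @return data.frame with one row per cell and columns `participant_id,
#'   task, condition, p_inhib, ssrt, mean_ssd, p_go, rt_tot, rt_correct,
#'   rt_error, iiv_rt, gf_pct, n_go, n_stop`.
#' @examples
#' agent <- race_params(go = exgauss_params(361, 63, 85),
#'                      stop = exgauss_params(109, 36, 34), tf = 0.05)
#' trials <- run_session(session_config("classical", "control"), agent, seed = 1)
#' subject_summaries(trials)
#' @export
subject_summaries <- function(records) {
  key <- interaction(records$participant_id, records$task, records$condition,
                     drop = TRUE)
  rows <- lapply(split(records, key), function(r) {
    rs <- rt_summaries(r)
    st <- r[r$trial_type == "stop", ]
    data.frame(participant_id = r$participant_id[1], task = r$task[1],
               condition = r$condition[1],
               p_inhib = if (nrow(st)) p_inhib(r) else NA_real_,
               ssrt = tryCatch(ssrt_quantile(r), error = function(e) NA_real_),
               mean_ssd = if (nrow(st)) mean(st$ssd_ms) else NA_real_,
               p_go = rs$p_go, rt_tot = rs$rt_tot, rt_correct = rs$rt_correct,
               rt_error = rs$rt_error, iiv_rt = rs$iiv_rt, gf_pct = rs$gf_pct,
               n_go = sum(r$trial_type == "go"), n_stop = nrow(st),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$participant_id, out$task, out$condition), , drop = FALSE]
}

#' Participant exclusion rules for reliable SSRT estimation
#'
#' A participant cell is excluded when any of three criteria holds:
#' (i) inhibition accuracy below 25% or above 75% (the staircase failed to
#' track mid-range inhibition); (ii) go-failure percentage above 40%;
#' (iii) a quantile-method SSRT estimate that is negative or below 75 ms.
#' All violated criteria are reported.
#'
#' @param summary a one-row data.frame or list with `p_inhib` (fraction),
#'   `gf_pct` (percent) and `ssrt` (ms), e.g. one row of
#'   [subject_summaries()].
#' @return list with `include` (logical) and `reasons` (character vector of
#'   violated criteria, empty when included).
#' @examples
#' exclusion_filter(list(p_inhib = 0.20, gf_pct = 1, ssrt = 150))
#' @export
exclusion_filter <- function(summary) {
  reasons <- character(0)
  if (is.na(summary$p_inhib) || summary$p_inhib < 0.25 || summary$p_inhib > 0.75)
    reasons <- c(reasons, "(i) P_inhib outside [25%, 75%]")
  if (is.na(summary$gf_pct) || summary$gf_pct > 40)
    reasons <- c(reasons, "(ii) go-failure rate above 40%")
  if (is.na(summary$ssrt) || summary$ssrt < 75)
    reasons <- c(reasons, "(iii) SSRT estimate negative or below 75 ms")
  list(include = length(reasons) == 0, reasons = reasons)
}

#' @rdname exclusion_filter
#' @param summaries a [subject_summaries()] data.frame.
#' @return `exclusion_report()`: the input with `include` and `reasons`
#'   columns appended (reasons collapsed with "; ").
#' @export
exclusion_report <- function(summaries) {
  res <- lapply(seq_len(nrow(summaries)), function(i)
    exclusion_filter(summaries[i, ]))
  summaries$include <- vapply(res, `[[`, logical(1), "include")
  summaries$reasons <- vapply(res, function(r)
    paste(r$reasons, collapse = "; "), character(1))
  summaries
}
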