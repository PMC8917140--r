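# Shared fixture builders; all data is generated in code.

table2_go <- function() exgauss_params(361, 63, 85)       # calibrated go side
table2_stop <- function() exgauss_params(109, 36, 34)     # classical control

default_race_agent <- function(tf = 0.05, gf = 0.003)
  race_params(go = table2_go(), stop = table2_stop(), tf = tf, gf = gf)

default_ddm <- function() ddm_params(a = 1.78, v = 4, t0 = 224, z = 0.51)

# Hand-constructed single-cell record frame: `go_rt` responded go trials
# (correct unless listed in `go_errors`), `go_omit` omitted go trials,
# `sr` data.frame(rt, ssd) signal-respond trials, `inh_ssd` SSDs of
# successfully inhibited stop trials.
toy_records <- function(go_rt = numeric(0), go_omit = 0,
                        sr = data.frame(rt = numeric(0), ssd = numeric(0)),
                        inh_ssd = numeric(0), go_errors = integer(0),
                        participant_id = "P01", task = "classical",
                        condition = "control") {
  n <- length(go_rt) + go_omit + nrow(sr) + length(inh_ssd)
  rows <- list()
  add <- function(type, ssd, resp, rt, corr)
    data.frame(participant_id = participant_id, task = task,
               condition = condition, trial_index = 0L, trial_type = type,
               stimulus = "circle", ssd_ms = ssd, response = resp, rt_ms = rt,
               correct = corr, stringsAsFactors = FALSE)
  for (i in seq_along(go_rt))
    rows[[length(rows) + 1]] <- add("go", NA_real_,
                                    if (i %in% go_errors) "right" else "left",
                                    go_rt[i], !(i %in% go_errors))
  if (go_omit > 0) for (i in seq_len(go_omit))
    rows[[length(rows) + 1]] <- add("go", NA_real_, "none", NA_real_, NA)
  for (i in seq_len(nrow(sr)))
    rows[[length(rows) + 1]] <- add("stop", sr$ssd[i], "left", sr$rt[i], TRUE)
  for (s in inh_ssd)
    rows[[length(rows) + 1]] <- add("stop", s, "none", NA_real_, NA)
  out <- do.call(rbind, rows)
  out$trial_index <- seq_len(nrow(out)) - 1L
  out
}
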