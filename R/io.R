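trial_columns <- c("participant_id", "task", "condition", "trial_index",
                   "trial_type", "stimulus", "ssd_ms", "response", "rt_ms",
                   "correct")

#' Read and write trial-level CSV files
#'
#' The trial table is a UTF-8, comma-delimited CSV with header
#' `participant_id,task,condition,trial_index,trial_type,stimulus,ssd_ms,response,rt_ms,correct`
#' and '.' as decimal mark. Absent values (`ssd_ms` on go trials, `rt_ms` and
#' `correct` on unresponded trials) are empty cells. `read_trials()` validates
#' the schema and the structural invariants -- go trials carry no SSD,
#' unresponded trials carry no RT, RTs are positive -- and reports the file
#' line number of every violation. Write-then-read round-trips losslessly.
#'
#' @param path file path.
#' @param records trial data.frame (see [run_session()]).
#' @return `read_trials()` a validated trial data.frame; `write_trials()`
#'   the path, invisibly.
#' @examples
#' agent <- race_params(go = exgauss_params(361, 63, 85),
#'                      stop = exgauss_params(109, 36, 34))
#' trials <- run_session(session_config("classical", "control"), agent, seed = 1)
#' f <- tempfile(fileext = ".csv")
#' write_trials(trials, f)
#' identical(read_trials(f)$rt_ms, trials$rt_ms)
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- gsub("\"", "", strsplit(readLines(path, n = 1), ",", fixed = TRUE)[[1]])
  if (!identical(header, trial_columns))
    stop("bad trial CSV header; expected exactly: ",
         paste(trial_columns, collapse = ","), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(participant_id = "character",
                                       task = "character",
                                       condition = "character",
                                       trial_index = "integer",
                                       trial_type = "character",
                                       stimulus = "character",
                                       ssd_ms = "numeric",
                                       response = "character",
                                       rt_ms = "numeric",
                                       correct = "logical"),
                        na.strings = "")
  if (nrow(df) == 0) return(df)
  line <- seq_len(nrow(df)) + 1L  # header is line 1
  fail <- function(cond, what) {
    if (any(cond))
      stop(sprintf("invalid trial record(s) at line(s) %s: %s",
                   paste(utils::head(line[cond], 5), collapse = ", "), what),
           call. = FALSE)
  }
  fail(!df$task %in% c("classical", "sensorial"), "unknown task")
  fail(!df$condition %in% c("control", "canal", "otolith"), "unknown condition")
  fail(!df$trial_type %in% c("go", "stop"), "unknown trial_type")
  fail(!df$response %in% c("left", "right", "none"), "unknown response")
  fail(df$trial_type == "go" & !is.na(df$ssd_ms), "ssd_ms set on a go trial")
  fail(df$trial_type == "stop" & is.na(df$ssd_ms), "stop trial without ssd_ms")
  fail(df$response == "none" & !is.na(df$rt_ms), "rt_ms set without a response")
  fail(df$response != "none" & is.na(df$rt_ms), "responded trial without rt_ms")
  fail(!is.na(df$rt_ms) & df$rt_ms <= 0, "non-positive rt_ms")
  fail(df$response != "none" & is.na(df$correct), "responded trial without correct")
  df
}

#' @rdname read_trials
#' @export
write_trials <- function(records, path) {
  missing_cols <- setdiff(trial_columns, names(records))
  if (length(missing_cols))
    stop("records lack column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  utils::write.csv(records[trial_columns], path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write / read a study blueprint as YAML
#'
#' @param blueprint a [study_blueprint()].
#' @param path file path.
#' @return `write_blueprint()` the path invisibly; `read_blueprint()` the
#'   blueprint.
#' @export
write_blueprint <- function(blueprint, path) {
  stopifnot(inherits(blueprint, "study_blueprint"))
  obj <- list(n_participants = blueprint$n_participants,
              seed = blueprint$seed,
              shared_subject_effect = blueprint$shared_subject_effect,
              cells = blueprint$cells,
              params = lapply(blueprint$params, function(cell)
                lapply(cell, function(p) as.list(p))))
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_blueprint
#' @export
read_blueprint <- function(path) {
  obj <- yaml::read_yaml(path)
  bp <- study_blueprint(n_participants = obj$n_participants,
                        seed = obj$seed,
                        cells = as.data.frame(obj$cells,
                                              stringsAsFactors = FALSE),
                        shared_subject_effect = obj$shared_subject_effect %||% 0)
  bp$params <- lapply(obj$params, function(cell)
    lapply(cell, function(p) c(mean = p$mean, sd = p$sd)))
  bp
}
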