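#' Construct and validate a per-trial event table
#'
#' One row per trial. Times are in seconds; `t_move` is the produced
#' movement-onset time measured from cue offset (positive), `t_stim` the
#' stimulus presentation time relative to movement onset (signed, negative =
#' before the movement). `outcome` codes the binary perceptual report
#' (1 = correct, 0 = incorrect).
#'
#' @param subject_id subject identifier (coerced to character).
#' @param trial_id integer trial identifier, unique within subject.
#' @param condition movement timing condition, `"short"` or `"long"`.
#' @param t_move movement-onset time from cue offset, seconds, > 0.
#' @param t_stim stimulus time relative to movement onset, seconds.
#' @param outcome binary outcome, 0 or 1.
#' @return a `data.frame` of class `trial_table`.
#' @export
trial_table <- function(subject_id, trial_id, condition, t_move, t_stim, outcome) {
  tt <- data.frame(
    subject_id = as.character(subject_id),
    trial_id = as.integer(trial_id),
    condition = as.character(condition),
    t_move = as.numeric(t_move),
    t_stim = as.numeric(t_stim),
    outcome = as.integer(outcome),
    stringsAsFactors = FALSE
  )
  class(tt) <- c("trial_table", "data.frame")
  validate_trial_table(tt)
}

#' @rdname trial_table
#' @param tt a candidate trial table.
#' @export
validate_trial_table <- function(tt) {
  required <- c("subject_id", "trial_id", "condition", "t_move", "t_stim", "outcome")
  missing <- setdiff(required, names(tt))
  if (length(missing) > 0) {
    stop("trial table is missing column(s): ", paste(missing, collapse = ", "))
  }
  if (!all(tt$outcome %in% c(0L, 1L))) stop("outcome must be 0 or 1")
  if (!all(tt$condition %in% c("short", "long"))) {
    stop("condition must be 'short' or 'long'")
  }
  if (any(tt$t_move <= 0)) stop("t_move must be positive")
  dup <- duplicated(tt[, c("subject_id", "trial_id")])
  if (any(dup)) stop("trial_id must be unique within subject")
  if (!inherits(tt, "trial_table")) class(tt) <- c("trial_table", "data.frame")
  tt
}

#' Read / write a trial table as tab-separated text
#'
#' Fixed header `subject_id  trial_id  condition  t_move  t_stim  outcome`,
#' UTF-8, '.' decimal separator. Numeric columns are written with 17
#' significant digits so that a write/read round trip reproduces doubles
#' exactly.
#'
#' @param path file path.
#' @return `read_trial_table` returns a validated [trial_table()];
#'   `write_trial_table` returns `path` invisibly.
#' @export
read_trial_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, colClasses = c(
    subject_id = "character", trial_id = "integer", condition = "character",
    t_move = "numeric", t_stim = "numeric", outcome = "integer"
  ))
  validate_trial_table(df)
}

#' @rdname read_trial_table
#' @param tt a [trial_table()].
#' @export
write_trial_table <- function(tt, path) {
  tt <- validate_trial_table(tt)
  out <- tt
  out$t_move <- vapply(tt$t_move, function(x) format(x, digits = 17), "")
  out$t_stim <- vapply(tt$t_stim, function(x) format(x, digits = 17), "")
  utils::write.table(out, path,
    sep = "\t", quote = FALSE, row.names = FALSE,
    fileEncoding = "UTF-8"
  )
  invisible(path)
}

#' Select trials entering the phase-outcome analyses
#'
#' Three selection rules used by the prediction analyses:
#' * `"analysis_window"`: stimuli within 0.6 s of movement onset
#'   (`|t_stim| <= 0.6`, inclusive bound);
#' * `"forward_only"`: additionally only trials whose stimulus follows the
#'   phase-estimation time (`t_stim > phase_time`), so the phase is always
#'   extrapolated forward in time — the pre-stimulus control;
#' * `"pre_movement"`: stimuli preceding movement onset (`t_stim < 0`) — the
#'   stimulus-locked control.
#'
#' Each rule is idempotent.
#'
#' @param trials a [trial_table()].
#' @param mode one of `"analysis_window"`, `"forward_only"`, `"pre_movement"`.
#' @param phase_time phase-estimation time in seconds relative to movement
#'   onset; required for `mode = "forward_only"`.
#' @param window half-open analysis half-width override (seconds, default 0.6).
#' @return the filtered trial table (possibly empty, with a warning).
#' @export
filter_trials <- function(trials, mode = c("analysis_window", "forward_only", "pre_movement"),
                          phase_time = NULL, window = 0.6) {
  mode <- match.arg(mode)
  trials <- validate_trial_table(trials)
  keep <- switch(mode,
    analysis_window = abs(trials$t_stim) <= window,
    forward_only = {
      if (is.null(phase_time)) stop("mode 'forward_only' requires phase_time")
      abs(trials$t_stim) <= window & trials$t_stim > phase_time
    },
    pre_movement = abs(trials$t_stim) <= window & trials$t_stim < 0
  )
  out <- trials[keep, , drop = FALSE]
  if (nrow(out) == 0) warning("trial selection '", mode, "' returned no trials")
  rownames(out) <- NULL
  out
}
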