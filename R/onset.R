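#' A raw force (joystick voltage) trace
#'
#' @param samples numeric vector of voltage samples, finite.
#' @param fs sampling rate, Hz (1000 in the reference setup).
#' @return an object of class `force_trace`.
#' @export
force_trace <- function(samples, fs = 1000) {
  if (!all(is.finite(samples))) stop("force trace contains non-finite values")
  if (fs <= 0) stop("fs must be positive")
  structure(list(samples = as.numeric(samples), fs = fs), class = "force_trace")
}

#' Detect movement onset in a force trace
#'
#' Movement onset is the first sample of the first run of at least
#' `run_length` consecutive samples whose first (forward) difference is
#' strictly positive, i.e. the first index `i` such that
#' `x[i + k] - x[i + k - 1] > 0` for `k = 1, ..., run_length`. The rule
#' operates on raw differences (no smoothing); a zero difference breaks the
#' run.
#'
#' @param trace a [force_trace()] (or numeric vector, taken at `fs` Hz).
#' @param run_length required run of positive differences (default 15).
#' @param fs sampling rate when `trace` is a bare numeric vector.
#' @return a list with `index` (1-based sample index) and `time`
#'   (`index / fs`, seconds).
#' @export
#' @examples
#' tr <- force_trace(c(rep(0, 20), cumsum(seq_len(30))), fs = 1000)
#' detect_movement_onset(tr, run_length = 15)
detect_movement_onset <- function(trace, run_length = 15, fs = 1000) {
  if (is.numeric(trace)) trace <- force_trace(trace, fs)
  x <- trace$samples
  if (length(x) < run_length + 1) {
    stop("trace too short: need at least run_length + 1 = ", run_length + 1, " samples")
  }
  pos <- diff(x) > 0
  r <- rle(pos)
  ends <- cumsum(r$lengths)
  hit <- which(r$values & r$lengths >= run_length)
  if (length(hit) == 0) stop("no onset detected")
  idx <- ends[hit[1]] - r$lengths[hit[1]] + 1
  list(index = idx, time = idx / trace$fs)
}
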