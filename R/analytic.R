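#' Complex analytic epochs at a stated center frequency
#'
#' @param values complex array channels x samples x trials.
#' @param fs_out sampling rate of the (possibly downsampled) series, Hz.
#' @param time sample times, seconds.
#' @param center_freq band center frequency, Hz.
#' @param band length-2 numeric, pass band (Hz); must straddle `center_freq`.
#' @param channel_labels character vector.
#' @return an object of class `analytic_epochs`.
#' @export
analytic_epochs <- function(values, fs_out, time, center_freq, band,
                            channel_labels = NULL) {
  if (length(dim(values)) != 3) stop("values must be a 3-d array")
  if (length(time) != dim(values)[2]) stop("time axis does not match sample dimension")
  if (!(band[1] < center_freq && center_freq < band[2])) {
    stop("band must straddle the center frequency")
  }
  if (is.null(channel_labels)) channel_labels <- paste0("ch", seq_len(dim(values)[1]))
  structure(
    list(
      values = values, fs_out = fs_out, time = time,
      center_freq = center_freq, band = band, channel_labels = channel_labels
    ),
    class = "analytic_epochs"
  )
}

#' @export
print.analytic_epochs <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<analytic_epochs> %d ch x %d samples x %d trials, %g Hz center ([%g, %g] Hz), fs_out = %g Hz\n",
    d[1], d[2], d[3], x$center_freq, x$band[1], x$band[2], x$fs_out
  ))
  invisible(x)
}

# analytic signal of the columns of a real matrix, standard FFT construction:
# zero the negative frequencies, double the positive ones
analytic_signal <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::mvfft(stats::mvfft(x) * h, inverse = TRUE) / n
}

#' Band-pass filter epochs and compute the analytic signal
#'
#' Two-pass (zero-phase) Butterworth band-pass of the stated order per pass
#' (default 3rd order, 3-5 Hz), followed by the analytic signal (Hilbert
#' transform) per channel and trial, edge-protected by reflection padding,
#' then cut to `window` and downsampled to `fs_out` by decimation of the
#' complex series. Phase is the argument of the result (cosine phase, 0 at a
#' signal peak), amplitude its modulus.
#'
#' @param epochs an [epoch_set()]; its time axis must cover `window`.
#' @param band length-2 numeric pass band, Hz.
#' @param order filter order per pass.
#' @param fs_out output sampling rate, Hz; must divide `epochs$fs`.
#' @param window length-2 numeric, output window (s), default \[-1.9, 0\].
#' @param center_freq stated center frequency; default `mean(band)`.
#' @return an [analytic_epochs()] object.
#' @export
bandpass_analytic <- function(epochs, band = c(3, 5), order = 3, fs_out = 200,
                              window = c(-1.9, 0), center_freq = mean(band)) {
  epochs <- validate_epoch_set(epochs)
  fs <- epochs$fs
  if (band[1] <= 0 || band[2] >= fs / 2) stop("band must lie inside (0, fs/2)")
  if (abs(fs / fs_out - round(fs / fs_out)) > 1e-9) stop("fs_out must divide fs")
  dec <- as.integer(round(fs / fs_out))
  n <- length(epochs$time)
  min_n <- ceiling(3 * fs / band[1])
  if (n < min_n) {
    stop(
      "epoch too short for stable filtering: need >= ", min_n,
      " samples (3 cycles of the band's low edge)"
    )
  }
  if (epochs$time[1] > window[1] + 1e-9 || epochs$time[n] < window[2] - 1e-9) {
    stop("epochs do not cover the requested output window")
  }
  bf <- signal::butter(order, band / (fs / 2), type = "pass")
  pad <- min(n - 1, ceiling(1.5 * fs / band[1]))
  d <- dim(epochs$data)
  # flatten trials x channels into columns for one vectorized filter+Hilbert pass
  xm <- matrix(aperm(epochs$data, c(2, 1, 3)), nrow = n)
  xp <- rbind(
    xm[(pad + 1):2, , drop = FALSE],
    xm,
    xm[(n - 1):(n - pad), , drop = FALSE]
  )
  yf <- apply(xp, 2, function(col) signal::filtfilt(bf, col))
  h <- analytic_signal(yf)[(pad + 1):(pad + n), , drop = FALSE]
  # cut to window and decimate on the integer sample grid (keeps t = 0 exact)
  counts <- round(epochs$time * fs)
  keep <- which(epochs$time >= window[1] - 1e-9 & epochs$time <= window[2] + 1e-9 &
    counts %% dec == 0)
  hw <- h[keep, , drop = FALSE]
  values <- aperm(
    array(hw, dim = c(length(keep), d[1], d[3])),
    c(2, 1, 3)
  )
  analytic_epochs(values, fs_out, counts[keep] / fs, center_freq, band,
    channel_labels = epochs$channel_labels
  )
}

#' Sliding frequency grid for frequency-resolved analysis
#'
#' Centers from `lo` to `hi` in steps of `step` (truncated below `hi` when
#' `step` does not divide the range), each with a pass band `center +/-
#' width/2`.
#'
#' @param lo,hi first and last center frequency, Hz.
#' @param step center spacing, Hz.
#' @param width band width, Hz (> 0).
#' @return data.frame with columns `center`, `lo`, `hi`.
#' @export
#' @examples
#' frequency_grid() # 25 bands, 3.5..15.5 Hz
frequency_grid <- function(lo = 3.5, hi = 15.5, step = 0.5, width = 2) {
  if (lo > hi) stop("lo must not exceed hi")
  if (width <= 0) stop("width must be positive")
  centers <- seq(lo, hi, by = step)
  data.frame(center = centers, lo = centers - width / 2, hi = centers + width / 2)
}

#' Time-frequency power, normalized per frequency
#'
#' For each band of `grid`, band-passes the epochs, averages the squared
#' modulus of the analytic signal over trials and channels, and divides each
#' frequency row by its mean over the analysis window so every row has unit
#' mean.
#'
#' @param epochs an [epoch_set()] covering `window`.
#' @param grid a [frequency_grid()] data.frame.
#' @param window analysis window (s).
#' @param fs_out output sampling rate passed to [bandpass_analytic()].
#' @param order filter order per pass.
#' @return list with `power` (frequency x time matrix, unit row means),
#'   `freq` (centers) and `time`.
#' @export
tf_power <- function(epochs, grid = frequency_grid(), window = c(-1.9, 0),
                     fs_out = epochs$fs, order = 3) {
  if (dim(epochs$data)[3] < 1) stop("tf_power requires at least one trial")
  rows <- vector("list", nrow(grid))
  tim <- NULL
  for (k in seq_len(nrow(grid))) {
    ae <- bandpass_analytic(epochs,
      band = c(grid$lo[k], grid$hi[k]), order = order,
      fs_out = fs_out, window = window, center_freq = grid$center[k]
    )
    pw <- apply(Mod(ae$values)^2, 2, mean) # over channels and trials
    rows[[k]] <- pw / mean(pw)
    tim <- ae$time
  }
  list(power = do.call(rbind, rows), freq = grid$center, time = tim)
}
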