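#' Binned movement-aligned performance time course
#'
#' Percent-correct in sliding bins of `binwidth` stepped by `step` over
#' `window` (stimulus time relative to movement onset). Bins are half-open
#' `[left, left + binwidth)`; the final bin includes its right edge. With the
#' default 0.05/0.025 s geometry each interior trial contributes to exactly
#' two bins. Bins with fewer than `min_per_bin` trials are flagged `thin`.
#'
#' @param trials a [trial_table()] (pooled as the caller requires).
#' @param window length-2 numeric, bin range (s).
#' @param binwidth bin size (s).
#' @param step bin step (s).
#' @param min_per_bin minimum trials per bin before flagging.
#' @return data.frame with columns `center`, `left`, `right`, `n`,
#'   `pct_correct` (NA for empty bins) and `thin`.
#' @export
bin_performance <- function(trials, window = c(-0.575, 0.475), binwidth = 0.05,
                            step = 0.025, min_per_bin = 5) {
  edges <- bin_edges(window, binwidth, step)
  left <- edges$left
  right <- edges$right
  nb <- length(left)
  n <- integer(nb)
  pct <- rep(NA_real_, nb)
  for (k in seq_len(nb)) {
    inbin <- trials$t_stim >= left[k] &
      (trials$t_stim < right[k] | (k == nb & trials$t_stim <= right[k]))
    n[k] <- sum(inbin)
    if (n[k] > 0) pct[k] <- 100 * mean(trials$outcome[inbin])
  }
  if (all(n == 0)) stop("all performance bins are empty")
  data.frame(
    center = left + binwidth / 2, left = left, right = right,
    n = n, pct_correct = pct, thin = n < min_per_bin
  )
}

# bin edges as exact integer multiples of step where possible, so that edges
# meant to coincide with 0 (or each other) do so exactly in floating point
bin_edges <- function(window, binwidth, step) {
  nb <- length(seq(window[1], window[2] - binwidth + 1e-12, by = step))
  k0 <- round(window[1] / step)
  if (abs(k0 * step - window[1]) < 1e-9 && abs(binwidth / step - round(binwidth / step)) < 1e-9) {
    left <- (k0 + 0:(nb - 1)) * step
    right <- (k0 + 0:(nb - 1) + round(binwidth / step)) * step
  } else {
    left <- window[1] + step * (0:(nb - 1))
    right <- left + binwidth
  }
  list(left = left, right = right)
}

# membership matrix (bins x trials) for the sliding-bin geometry; fixed across
# outcome permutations since it depends only on the stimulus times
bin_membership <- function(t_stim, window, binwidth, step) {
  edges <- bin_edges(window, binwidth, step)
  left <- edges$left
  right <- edges$right
  nb <- length(left)
  M <- matrix(FALSE, nb, length(t_stim))
  for (k in seq_len(nb)) {
    M[k, ] <- t_stim >= left[k] &
      (t_stim < right[k] | (k == nb & t_stim <= right[k]))
  }
  list(M = M, center = left + binwidth / 2)
}

# linear interpolation across thin/empty bins (FFT path needs a complete series)
interp_thin <- function(x, thin) {
  bad <- thin | !is.finite(x)
  if (!any(bad)) {
    return(x)
  }
  if (all(bad)) stop("no usable performance bins")
  idx <- seq_along(x)
  stats::approx(idx[!bad], x[!bad], xout = idx, rule = 2)$y
}

#' Random-effects spectral analysis of movement-aligned performance
#'
#' For each subject and frequency `f`, fits the logistic regression
#' `P(correct) = plogis(b0 + b1 sin(2 pi f t) + b2 cos(2 pi f t))` of the
#' outcome on the phase `2 pi f t` of a movement-locked sinusoid (`t` =
#' stimulus time relative to movement onset), then tests the subject-level
#' `(b1, b2)` pairs against zero with [hotelling_t2()] and summarizes them as
#' predictive value, jackknife SE and optimal phase. P-values are reported
#' uncorrected across frequencies.
#'
#' @param trials a [trial_table()] with a `subject_id` column spanning the
#'   group.
#' @param freqs frequency grid, Hz.
#' @return data.frame of class `behavior_spectrum` with one row per
#'   frequency: `freq`, `pv`, `se`, `t2`, `p`, `phi_opt`, `n_subjects`;
#'   attribute `method = "random_effects"`.
#' @export
behavior_spectrum_random_effects <- function(trials, freqs = seq(2.5, 14.5, by = 0.5)) {
  trials <- validate_trial_table(trials)
  subjects <- unique(trials$subject_id)
  rows <- lapply(freqs, function(f) {
    fits <- lapply(subjects, function(s) {
      tt <- trials[trials$subject_id == s, ]
      fit_phase_outcome_model(2 * pi * f * tt$t_stim, tt$outcome, min_trials = 10)
    })
    conv <- vapply(fits, function(x) x$converged, logical(1))
    if (!all(conv)) {
      warning(sum(!conv), " subject fit(s) did not converge at ", f, " Hz; excluded")
    }
    b <- do.call(rbind, lapply(fits[conv], function(x) c(x$beta1, x$beta2)))
    ht <- hotelling_t2(b)
    pv <- predictive_value(b)
    data.frame(
      freq = f, pv = pv$pv, se = jackknife_se(b), t2 = ht$t2, p = ht$p,
      phi_opt = pv$phi_opt, n_subjects = nrow(b)
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "method") <- "random_effects"
  class(out) <- c("behavior_spectrum", "data.frame")
  out
}

#' Fixed-effects FFT/permutation spectral analysis of pooled performance
#'
#' Pools all trials, bins percent-correct with [bin_performance()], demeans
#' the series, tapers it with a Hann window, and evaluates its power on the
#' requested frequency grid by zero-padded Fourier transform. The null
#' distribution is obtained by permuting the pairing of stimulus times and
#' outcomes (`n_perm` times) and re-running the identical binning/taper/FFT
#' chain; `p = (1 + #(null >= observed)) / (n_perm + 1)` per frequency, with
#' a BH-FDR mask across frequencies. Thin bins (fewer than `min_per_bin`
#' trials) are linearly interpolated before the FFT.
#'
#' @param trials pooled [trial_table()].
#' @param n_perm number of permutations (a warning is issued below 100).
#' @param seed integer seed.
#' @param freqs evaluation frequencies, Hz (must be multiples of the padded
#'   resolution `1 / (step * n_pad)` to be exact; the default 0.5 Hz grid is).
#' @param q FDR level for the significance mask.
#' @inheritParams bin_performance
#' @return data.frame of class `behavior_spectrum`: `freq`, `power`, `p`,
#'   `significant`; attributes `method = "fft_permutation"`, `binned`
#'   (observed series) and `n_perm`.
#' @export
behavior_spectrum_fft_permutation <- function(trials, n_perm = 5000, seed = 1,
                                              freqs = seq(2.5, 14.5, by = 0.5),
                                              window = c(-0.575, 0.475),
                                              binwidth = 0.05, step = 0.025,
                                              min_per_bin = 5, q = 0.05) {
  trials <- validate_trial_table(trials)
  if (n_perm < 100) warning("n_perm < 100: permutation p-values will be unstable")
  bm <- bin_membership(trials$t_stim, window, binwidth, step)
  M <- bm$M
  counts <- rowSums(M)
  thin <- counts < min_per_bin
  nb <- nrow(M)
  taper <- 0.5 * (1 - cos(2 * pi * (0:(nb - 1)) / (nb - 1))) # Hann
  # zero-padded DFT on the exact evaluation grid == exponential sum over bins
  E <- exp(-2i * pi * outer(freqs, (0:(nb - 1)) * step))
  series_power <- function(y_mat) {
    pct <- 100 * (M %*% y_mat) / counts # NaN for empty bins
    pct <- apply(pct, 2, interp_thin, thin = thin)
    x <- sweep(pct, 2, colMeans(pct)) * taper
    Mod(E %*% x)^2
  }
  obs_series <- 100 * drop(M %*% trials$outcome) / counts
  obs <- drop(series_power(matrix(trials$outcome, ncol = 1)))
  set.seed(seed)
  nt <- nrow(trials)
  perm_idx <- vapply(seq_len(n_perm), function(k) sample.int(nt), integer(nt))
  null_pow <- series_power(matrix(trials$outcome[perm_idx], nrow = nt))
  p <- (1 + rowSums(null_pow >= obs)) / (n_perm + 1)
  out <- data.frame(freq = freqs, power = obs, p = p, significant = fdr_bh(p, q))
  attr(out, "method") <- "fft_permutation"
  attr(out, "binned") <- data.frame(center = bm$center, pct_correct = obs_series, thin = thin)
  attr(out, "n_perm") <- n_perm
  class(out) <- c("behavior_spectrum", "data.frame")
  out
}
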