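#' Configuration of the synthetic experiment
#'
#' Defaults follow the reference paradigm: instructed movement intervals of
#' 1.5 s ("short") and 2.3 s ("long") with produced-onset SDs of 0.20 and
#' 0.24 s; stimulus times drawn uniformly from -0.35 to +0.25 s around the
#' instructed movement time; a ~4 Hz oscillation phase-locked to movement
#' onset, carried by Gaussian-envelope bursts (by default one early burst at
#' -1.4 s and one late burst at -0.05 s) riding on 1/f background noise; and
#' binary outcomes drawn from a logistic model of the oscillation's phase at
#' stimulus time, with baseline log-odds `beta0 = qlogis(0.75)` (the
#' threshold-level 75% correct rate), effect magnitude `kappa` and optimal
#' phase `phi_opt`.
#'
#' Bursts are given as a list of lists with elements `center` (s), `width`
#' (Gaussian SD, s), `amplitude`, and optionally `phase_offset` (rad, added
#' to the subject's movement-locked angle) and `phase_jitter_sd` (rad;
#' trial-level von-Mises-free Gaussian jitter, `Inf` = uniform random phase
#' per trial, i.e. no locking). `couple_burst` names the burst whose phase
#' drives the outcome model.
#'
#' @param n_subjects number of subjects.
#' @param n_trials trials per subject.
#' @param instructed named numeric, instructed intervals (s).
#' @param onset_sd named numeric, SD of produced movement-onset times (s).
#' @param stim_jitter length-2 numeric, uniform stimulus-time interval
#'   relative to the instructed movement time (s).
#' @param n_channels number of EEG channels.
#' @param fs EEG sampling rate, Hz (must exceed `2 * f`).
#' @param epoch_window length-2 numeric, simulated epoch window relative to
#'   movement onset (s); must cover at least \[-1.9, 0\].
#' @param noise_exponent spectral exponent of the 1/f background.
#' @param noise_amplitude RMS amplitude of the background noise.
#' @param f oscillation center frequency, Hz.
#' @param bursts list of burst descriptors, see Details.
#' @param theta0 movement-locked phase angle at t = 0 (rad).
#' @param theta_subject_sd across-subject SD of the locked angle (rad).
#' @param couple_burst index of the burst driving outcomes.
#' @param beta0 baseline log-odds of a correct response.
#' @param kappa phase-effect magnitude (>= 0) on the log-odds scale.
#' @param phi_opt optimal phase (rad): phase at which P(correct) is maximal.
#' @param force_fs force-trace sampling rate, Hz.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 17, n_trials = 400,
                       instructed = c(short = 1.5, long = 2.3),
                       onset_sd = c(short = 0.20, long = 0.24),
                       stim_jitter = c(-0.35, 0.25),
                       n_channels = 8, fs = 200,
                       epoch_window = c(-2.4, 0.5),
                       noise_exponent = 1, noise_amplitude = 0.3,
                       f = 4,
                       bursts = list(
                         list(center = -1.4, width = 0.15, amplitude = 1),
                         list(center = -0.05, width = 0.15, amplitude = 1)
                       ),
                       theta0 = 0, theta_subject_sd = 0.2,
                       couple_burst = length(bursts),
                       beta0 = stats::qlogis(0.75), kappa = 0.8,
                       phi_opt = pi / 3,
                       force_fs = 1000) {
  cfg <- as.list(environment())
  if (cfg$n_subjects < 1 || cfg$n_trials < 1) stop("n_subjects and n_trials must be >= 1")
  if (cfg$kappa < 0) stop("kappa must be >= 0")
  if (diff(cfg$stim_jitter) <= 0) stop("stim_jitter must be a non-empty interval")
  if (cfg$fs <= 2 * cfg$f) stop("fs must exceed 2 * f")
  if (cfg$epoch_window[1] > -1.9 || cfg$epoch_window[2] < 0) {
    stop("epoch_window must cover at least [-1.9, 0] s")
  }
  for (b in cfg$bursts) {
    if (b$amplitude < 0) stop("burst amplitudes must be non-negative")
  }
  class(cfg) <- "sim_config"
  cfg
}

# per-trial latent phase of burst k at stimulus time, under the movement-locked
# phase convention: the oscillation's cosine phase is theta at t = 0
latent_phase_at_stim <- function(t_stim, f, theta) wrap_phase(theta + 2 * pi * f * t_stim)

#' Simulate a per-subject trial table with its latent stimulus phases
#'
#' Movement-onset times are Normal(instructed, SD) truncated to positive;
#' stimulus times are uniform in `stim_jitter` around the instructed time and
#' re-expressed relative to the produced movement onset. The latent phase at
#' stimulus is `theta + 2*pi*f*t_stim`, wrapped — the angle the EEG phase
#' extrapolation is meant to recover.
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @param subject_id subject label.
#' @param theta movement-locked phase angle for this subject (rad); defaults
#'   to `config$theta0` plus the coupled burst's `phase_offset`.
#' @return a [trial_table()] with extra columns `t_instructed` and
#'   `latent_phase` (phase of the coupled burst at stimulus time).
#' @export
simulate_trials <- function(config, seed, subject_id = "s01", theta = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  n <- config$n_trials
  if (is.null(theta)) {
    off <- config$bursts[[config$couple_burst]]$phase_offset
    theta <- config$theta0 + if (is.null(off)) 0 else off
  }
  condition <- sample(c("short", "long"), n, replace = TRUE)
  instr <- config$instructed[condition]
  t_move <- stats::rnorm(n, instr, config$onset_sd[condition])
  while (any(t_move <= 0)) { # truncate to positive support
    bad <- t_move <= 0
    t_move[bad] <- stats::rnorm(sum(bad), instr[bad], config$onset_sd[condition[bad]])
  }
  stim_rel_instr <- stats::runif(n, config$stim_jitter[1], config$stim_jitter[2])
  t_stim <- instr + stim_rel_instr - t_move
  phase <- latent_phase_at_stim(t_stim, config$f, theta)
  outcome <- simulate_outcomes(phase, config$beta0, config$kappa, config$phi_opt,
    seed = seed + 1L
  )
  tt <- trial_table(subject_id, seq_len(n), condition, t_move, t_stim, outcome)
  tt$t_instructed <- as.numeric(instr)
  tt$stim_rel_instructed <- stim_rel_instr
  tt$latent_phase <- phase
  tt
}

#' Draw binary outcomes from the phase-coupled logistic model
#'
#' `Y ~ Bernoulli(plogis(beta0 + kappa * cos(phase - phi_opt)))`. This is the
#' cosine-of-phase-difference parameterization of the sine/cosine regression
#' model, with `beta1 = kappa * sin(phi_opt)` (sine coefficient) and
#' `beta2 = kappa * cos(phi_opt)` (cosine coefficient); success probability
#' is maximal at `phase = phi_opt`.
#'
#' @param phase_at_stim numeric vector of phases (rad).
#' @param beta0 baseline log-odds.
#' @param kappa effect magnitude, >= 0.
#' @param phi_opt optimal phase (rad).
#' @param seed integer seed.
#' @return integer vector of 0/1 outcomes.
#' @export
simulate_outcomes <- function(phase_at_stim, beta0, kappa, phi_opt, seed) {
  if (!all(is.finite(c(beta0, kappa, phi_opt)))) stop("parameters must be finite")
  set.seed(seed)
  p <- stats::plogis(beta0 + kappa * cos(phase_at_stim - phi_opt))
  stats::rbinom(length(phase_at_stim), 1, p)
}

# 1/f^a Gaussian noise by spectral shaping of white noise; unit RMS
rnoise_1f <- function(n, fs, exponent = 1) {
  nf <- n %/% 2
  freqs <- (1:nf) * fs / n
  shape <- freqs^(-exponent / 2)
  sc <- complex(
    real = stats::rnorm(nf), imaginary = stats::rnorm(nf)
  ) * shape
  full <- complex(length.out = n)
  full[2:(nf + 1)] <- sc
  full[n:(n - nf + 2)] <- Conj(sc[1:(nf - 1)])
  x <- Re(stats::fft(full, inverse = TRUE)) / n
  x / stats::sd(x)
}

#' Simulate movement-aligned EEG epochs and force traces
#'
#' Each epoch is 1/f Gaussian background noise plus, for every configured
#' burst, a Gaussian-envelope oscillation
#' `amplitude * exp(-(t - center)^2 / (2 width^2)) * cos(2 pi f t + angle)`,
#' where `angle` is the subject's movement-locked phase (plus the burst's
#' `phase_offset` and trial-level `phase_jitter_sd` jitter if configured) —
#' the same phase convention as [simulate_trials()], so the extrapolated EEG
#' phase at stimulus time matches the latent outcome-generating phase up to
#' noise. Force traces are flat before movement onset and rise smoothly
#' (quadratically) from it.
#'
#' @param trials per-subject [trial_table()] (length sets the trial count).
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @param theta movement-locked base angle for this subject (rad), default
#'   `config$theta0`.
#' @return list with `epochs` (an [epoch_set()]), `forces` (list of
#'   [force_trace()], one per trial) and `onset_index` (configured onset
#'   sample per trial).
#' @export
simulate_eeg <- function(trials, config, seed, theta = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  if (is.null(theta)) theta <- config$theta0
  fs <- config$fs
  idx <- seq(round(config$epoch_window[1] * fs), round(config$epoch_window[2] * fs))
  time <- idx / fs
  ns <- length(time)
  n_tr <- nrow(trials)
  nc <- config$n_channels
  data <- array(0, dim = c(nc, ns, n_tr))
  for (i in seq_len(n_tr)) {
    osc <- numeric(ns)
    for (b in config$bursts) {
      ang <- theta + if (is.null(b$phase_offset)) 0 else b$phase_offset
      jsd <- if (is.null(b$phase_jitter_sd)) 0 else b$phase_jitter_sd
      if (is.infinite(jsd)) {
        ang <- stats::runif(1, -pi, pi)
      } else if (jsd > 0) {
        ang <- ang + stats::rnorm(1, 0, jsd)
      }
      env <- b$amplitude * exp(-(time - b$center)^2 / (2 * b$width^2))
      osc <- osc + env * cos(2 * pi * config$f * time + ang)
    }
    for (ch in seq_len(nc)) {
      noise <- config$noise_amplitude * rnoise_1f(ns, fs, config$noise_exponent)
      data[ch, , i] <- osc + noise
    }
  }
  ang_pos <- 2 * pi * (seq_len(nc) - 1) / nc
  pos <- cbind(cos(ang_pos), sin(ang_pos))
  epochs <- epoch_set(data, fs, time,
    channel_labels = sprintf("ch%02d", seq_len(nc)),
    channel_pos = pos, alignment = "movement"
  )
  forces <- vector("list", n_tr)
  onset_index <- integer(n_tr)
  ffs <- config$force_fs
  for (i in seq_len(n_tr)) {
    pre_n <- round(trials$t_move[i] * ffs)
    ramp_t <- (0:499) / ffs
    x <- c(rep(0, pre_n), 5 * ramp_t^2)
    forces[[i]] <- force_trace(x, ffs)
    onset_index[i] <- pre_n + 1L # first sample with positive forward difference
  }
  list(epochs = epochs, forces = forces, onset_index = onset_index)
}

#' Simulate a complete multi-subject dataset
#'
#' Orchestrates [simulate_trials()], [simulate_outcomes()] and
#' [simulate_eeg()] per subject, drawing each subject's movement-locked angle
#' as `theta0 + Normal(0, theta_subject_sd)` and using it consistently for
#' both the EEG bursts and the latent outcome-generating phase. Fully
#' deterministic for a fixed `config` and `seed`.
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @param eeg generate EEG/force data (set `FALSE` for behavior-only runs).
#' @return list of per-subject lists with elements `trials`, `theta`, and
#'   (if `eeg`) `epochs`, `forces`, `onset_index`.
#' @export
simulate_dataset <- function(config, seed, eeg = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  thetas <- config$theta0 + stats::rnorm(config$n_subjects, 0, config$theta_subject_sd)
  subj_seeds <- sample.int(2^30, 2 * config$n_subjects)
  out <- vector("list", config$n_subjects)
  for (s in seq_len(config$n_subjects)) {
    id <- sprintf("s%02d", s)
    off <- config$bursts[[config$couple_burst]]$phase_offset
    theta_couple <- thetas[s] + if (is.null(off)) 0 else off
    trials <- simulate_trials(config, subj_seeds[2 * s - 1], id, theta = theta_couple)
    rec <- list(trials = trials, theta = thetas[s])
    if (eeg) {
      rec <- c(rec, simulate_eeg(trials, config, subj_seeds[2 * s], theta = thetas[s]))
    }
    out[[s]] <- rec
  }
  names(out) <- sprintf("s%02d", seq_len(config$n_subjects))
  out
}
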