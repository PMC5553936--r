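# shared fixtures built in code

# epoch_set holding one waveform replicated over channels/trials
wave_epochs <- function(waveform, fs = 200, window = c(-2.4, 0.5),
                        n_channels = 2, n_trials = 1) {
  idx <- seq(round(window[1] * fs), round(window[2] * fs))
  tm <- idx / fs
  x <- waveform(tm)
  arr <- array(rep(x, each = 1), dim = c(1, length(tm), 1))
  arr <- array(0, dim = c(n_channels, length(tm), n_trials))
  for (ch in seq_len(n_channels)) for (tr in seq_len(n_trials)) arr[ch, , tr] <- x
  epoch_set(arr, fs, tm)
}

# analytic_epochs built directly from a complex channels x samples x trials array
analytic_from_array <- function(values, fs_out = 200, f = 4, band = c(3, 5),
                                t0 = -1.9) {
  nt <- dim(values)[2]
  analytic_epochs(values, fs_out, t0 + (seq_len(nt) - 1) / fs_out, f, band)
}

# analytic array with a fixed phase angle per trial (constant over channels/time)
analytic_unit_phases <- function(phases, n_channels = 4, n_samples = 5, fs_out = 200) {
  nt <- length(phases)
  v <- array(0i, dim = c(n_channels, n_samples, nt))
  for (i in seq_len(nt)) v[, , i] <- exp(1i * phases[i])
  analytic_from_array(v, fs_out = fs_out)
}

# quick trial table with given stimulus times/outcomes
quick_trials <- function(t_stim, outcome, subject_id = "s01",
                         condition = "short", t_move = 1.5) {
  n <- length(t_stim)
  trial_table(
    subject_id = rep(subject_id, length.out = n), trial_id = seq_len(n),
    condition = rep(condition, length.out = n),
    t_move = rep(t_move, length.out = n), t_stim = t_stim, outcome = outcome
  )
}
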