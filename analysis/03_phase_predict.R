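#!/usr/bin/env Rscript
# The core EEG analysis on synthetic ground truth: band-pass + analytic
# signal, extrapolation of measured phases to stimulus onset, and the
# group-level predictive-value map over channels and time, with the
# forward-extrapolation control at the peak time.

suppressMessages(library(phasebind))

SEED <- 23
dir.create("results", showWarnings = FALSE)

cfg <- sim_config(
  n_subjects = 17, n_trials = 120, n_channels = 4, noise_amplitude = 0.5,
  bursts = list(list(center = -0.05, width = 0.15, amplitude = 1)),
  couple_burst = 1, theta_subject_sd = 0.3
)
ds <- simulate_dataset(cfg, seed = SEED)
subjects <- lapply(ds, function(su) {
  list(analytic = bandpass_analytic(su$epochs), trials = su$trials)
})
cat(sprintf(
  "simulated %d subjects; late 4 Hz burst at %.2f s, true optimal phase %.3f rad\n",
  cfg$n_subjects, cfg$bursts[[1]]$center, cfg$phi_opt
))

map <- predict_timecourse(subjects, times = seq(-1.9, 0, by = 0.05))
write.table(map, "results/phase_predict_map.tsv",
  sep = "\t", quote = FALSE, row.names = FALSE
)
sig_times <- sort(unique(map$time[map$significant]))
peak <- map[which.max(map$pv), ]
cat(sprintf(
  "predictive value peaks at t = %.2f s (PV = %.2f +/- %.2f, p = %.2g)\n",
  peak$time, peak$pv, peak$se, peak$p
))
cat(sprintf(
  "FDR-significant times span [%.2f, %.2f] s; recovered optimal phase %.3f rad\n",
  min(sig_times), max(sig_times), peak$phi_opt
))

# forward-extrapolation control at the peak time: only trials whose stimulus
# follows the phase-estimation point
fwd <- predict_timecourse(subjects, times = peak$time, variant = "forward_only")
write.table(fwd, "results/phase_predict_forward_control.tsv",
  sep = "\t", quote = FALSE, row.names = FALSE
)
fpeak <- fwd[which.max(fwd$pv), ]
cat(sprintf(
  "forward-only control at t = %.2f s: PV = %.2f (vs %.2f) using >= %d trials/subject\n",
  peak$time, fpeak$pv, peak$pv, fpeak$n_trials_min
))
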