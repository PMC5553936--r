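---
title: "Movement-locked oscillatory phase and perceptual outcome: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Movement-locked oscillatory phase and perceptual outcome: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific question

When observers time a voluntary movement, visual sensitivity waxes and wanes
rhythmically in the theta range (~4 Hz), time-locked to the upcoming movement.
phasebind implements the statistical machinery to ask two questions on
trial-by-trial data:

1. Does the *phase* of a movement-locked ~4 Hz oscillation, measured in the
   EEG and extrapolated to the moment a near-threshold stimulus appears,
   predict whether the observer judges the stimulus correctly?
2. Is the ~4 Hz oscillation itself *phase-locked* to movement onset, and
   during which pre-movement epochs?

Everything is exercised on synthetic data with known ground truth; the
package deliberately contains no claims about any real dataset.

# The statistical model

## Phase as a circular predictor of a binary outcome

For trial $i$ with binary outcome $Y_i$ (1 = correct) and phase
$\varphi_i$ at stimulus time, the first-level model is the circular-linear
logistic regression

$$P(Y_i = 1) = \mathrm{logit}^{-1}\!\big[\beta_0 + \beta_1 \sin\varphi_i +
\beta_2 \cos\varphi_i\big],$$

fitted per subject by maximum likelihood (`fit_phase_outcome_model()`,
IRLS via `glm`). The pair $(\beta_1, \beta_2)$ is treated as one complex
effect. Equivalently $\beta_1 = \kappa \sin\varphi_{opt}$,
$\beta_2 = \kappa \cos\varphi_{opt}$: $\kappa$ is the modulation depth on
the log-odds scale and $\varphi_{opt}$ the phase of best performance. The
synthetic-data generator draws outcomes from exactly this model
(`simulate_outcomes()`), which makes $(\kappa, \varphi_{opt})$ identifiable
and parameter recovery testable. A brute-force reference fitter
(`fit_phase_outcome_grid()`, coarse grid plus Nelder–Mead on the exact
likelihood) shares no code with the IRLS route and is used as an
independent cross-check.

## Group-level inference

Subject-level pairs $(\beta_1, \beta_2)$ enter a bivariate Hotelling
$T^2$ test against zero (`hotelling_t2()`):
$T^2 = n\,\bar\beta' S^{-1} \bar\beta$, with the exact transformation
$F = \frac{n-2}{2(n-1)} T^2 \sim F_{2,\,n-2}$ under the null. The effect
size is the *predictive value* $PV = \lVert\bar\beta\rVert$
(`predictive_value()`), its uncertainty the leave-one-subject-out jackknife
$SE = \sqrt{\frac{n-1}{n}\sum_i (PV_{(-i)} - \overline{PV_{(\cdot)}})^2}$
(`jackknife_se()`), and the optimal phase
$\varphi_{opt} = \mathrm{atan2}(\bar\beta_1, \bar\beta_2)$. Multiple
comparisons across channels and time points are handled by
Benjamini–Hochberg FDR (`fdr_bh()`, delegated to `p.adjust`); condition
contrasts use a sign-flip permutation of each subject's matched complex
effects with the add-one convention, so the smallest attainable p-value is
$1/(n_{perm}+1)$.

## Phase measurement and extrapolation

EEG epochs are band-pass filtered 3–5 Hz with a two-pass (zero-phase)
third-order Butterworth filter, converted to the analytic signal (Hilbert
transform by the standard FFT construction), cut to $[-1.9, 0]$ s relative
to movement onset, and decimated to 200 Hz (`bandpass_analytic()`). Phase
follows the cosine convention (0 at a signal peak), wrapped to
$(-\pi, \pi]$ everywhere, including the simulator. The measured phase at
estimation time $t$ is projected to the stimulus time assuming a constant
carrier frequency $f$:

$$\varphi_i^{stim}(t) = \varphi_i(t) + 2\pi f\,(t^{stim}_i - t),$$

forward or backward in time (`extrapolate_phase()`). `predict_timecourse()`
assembles the full map: per channel and estimation time (default
$-1.9$ to $0$ s in 0.025 s steps), per subject, extrapolate, fit, then
Hotelling/PV/jackknife, with FDR across the space-by-time family (space
only when a single time point is analyzed, as in the single-timepoint
control variants). Variants: `forward_only` keeps trials whose stimulus
follows the estimation point (immune to stimulus-evoked activity);
`stimulus_locked` consumes stimulus-aligned epochs and skips extrapolation;
`joint_early_late_model()` fits both epochs' phases in one model so each
effect is partialled on the other.

## Phase locking to movement onset

Per channel and time, the mean resultant vector is the trial mean of the
analytic signal, $MRV_c(t) = \frac1n \sum_i H_{ic}(t)$ (`mrv()`);
amplitude-normalized it is the inter-trial coherence. The locking statistic
correlates MRV vectors across channels between two random half-splits of
the trials,

$$r(t) = \frac{\langle MRV^{(1)}(t), \overline{MRV^{(2)}(t)}\rangle}
{\lVert MRV^{(1)}(t)\rVert\,\lVert MRV^{(2)}(t)\rVert},$$

averaged as $\mathrm{Re}\,r(t)$ over 500 random partitions
(`split_half_spatial_corr()`); under no locking its expectation is zero.
Subjects' averaged $\mathrm{Re}\,r(t)$ enter a one-sample t-test per time
point with FDR across time (`group_phase_locking_test()`).

# The synthetic-data generator

`sim_config()` fixes the study conditions; `simulate_dataset()` draws, per
subject, a movement-locked angle $\theta_s = \theta_0 + N(0, 0.2^2)$ used
consistently by the EEG and the outcome model. Defaults:

| parameter | default | rationale |
|---|---|---|
| instructed intervals | 1.5 s / 2.3 s | the two movement-timing conditions |
| produced-onset SD | 0.20 / 0.24 s | matches the reported onset spread |
| stimulus jitter | $[-0.35, +0.25]$ s | uniform around the instructed time |
| carrier frequency | 4 Hz | center of the analysis band |
| bursts | $-1.4$ s and $-0.05$ s, Gaussian SD 0.15 s | the early/late non-monotonic profile |
| background | $1/f$, RMS 0.3 | standard EEG-like spectrum |
| outcome model | $\beta_0 = \mathrm{logit}(0.75)$, $\kappa = 0.8$, $\varphi_{opt} = \pi/3$ | threshold-level 2AFC performance with a clearly recoverable phase effect |
| epoch window | $[-2.4, +0.5]$ s | analysis window plus filter padding on both sides |

Force traces are flat before movement onset and rise quadratically from it,
so the 15-sample positive-derivative rule recovers the configured onset
exactly. Bursts may carry per-burst phase offsets and trial-level phase
jitter (`Inf` = no locking), which is how null and de-coupled early/late
scenarios are simulated.

What the generator does *not* emulate: volume conduction and realistic
topographies, eye/muscle artifacts, non-stationary noise, and — most
importantly — the signal-to-noise ratio of real scalp EEG, which is
unknown for this paradigm. Noise levels are chosen so that closure
properties (measured phase vs. latent generating phase, circular
correlation > 0.95 at high SNR) are testable at desk scale. Passing tests
therefore validate the *statistics*, not detectability in any real
recording.

# Numerical choices

* **Filter edges.** Epochs are reflection-padded (1.5 cycles of the band's
  low edge) before filtering and the analytic transform, then cut. Residual
  edge error for a pure in-band tone is < 0.05 rad at points at least
  ~0.6 s away from the raw epoch edges, and ~0.07 rad at the extreme
  $-1.9$ s sample of a $[-2.4, 0.5]$ s epoch; tests state these tolerances.
* **Temporal smearing.** A 3–5 Hz zero-phase filter has an impulse response
  several hundred ms long; burst-borne phase information therefore extends
  beyond the raw burst envelope in both directions. This is physics, not a
  bug: localization checks demand the effect at the burst core and its
  absence far away, not a razor-sharp boundary, and the phase-locking
  profile is tested as a pronounced mid-interval dip.
* **Downsampling.** The complex analytic signal is decimated on the integer
  sample grid (keeping $t = 0$ exact); decimating phases instead is
  indistinguishable in-band (tested to 0.02 rad).
* **Behavioral bins.** Sliding bins ($[-0.575, 0.475]$ s, width 0.05 s,
  step 0.025 s) are half-open with edges built as exact integer multiples
  of the step, so edges meant to coincide with 0 do so in floating point.
  The binned series is demeaned before Hann tapering (otherwise DC leakage
  corrupts the low frequencies and the constant-input identity fails) and
  evaluated on the 0.5 Hz grid by zero-padded DFT (padding to 80 bins of
  0.025 s, i.e. exactly the requested resolution). Bins with fewer than 5
  trials are linearly interpolated for the FFT path and flagged.
* **Degenerate fits.** Logistic fits need at least 30 trials (configurable)
  with both outcome classes; separation (pinned fitted probabilities or
  runaway coefficients) marks the fit non-converged and excludes it from
  group statistics with a warning. Cells with fewer than 3 converged
  subjects are masked, never fitted.
* **Hotelling edge cases.** An exactly zero mean gives $T^2 = 0$, $p = 1$
  regardless of the covariance; a singular covariance with nonzero mean is
  an error. The F reference is used rather than permutation — standard for
  $T^2$ against zero.
* **Split-half details.** Odd trial counts drop one trial uniformly at
  random per partition (seeded). The partition average is taken over
  $\mathrm{Re}\,r(t)$ as the group statistic; the complex mean is exposed
  for diagnostics. Zero-amplitude samples are excluded from normalized
  MRVs with a warning (they cannot arise in band-passed data).
* **Determinism.** Every stochastic routine takes an explicit seed;
  identical configuration and seed give bit-identical output.

# Problem sizes

The test suite and `scripts/acceptance.R` use sizes chosen for desk-scale
reproducibility: Hotelling null calibration with $10^4$ simulated groups of
17 subjects; parameter recovery on 5000 trials; end-to-end closure on
17-subject datasets (120 trials, 2 channels, 0.1 s time grid) over 50
replicates in the tests and 20 in the acceptance script; 500 null
simulations for the locking group test's familywise calibration (20
partitions, 16 trials, 5 near-independent time points); behavioral
detection on 4000 pooled trials with 1000 permutations. The analysis
drivers under `analysis/` use comparable sizes and finish in a few minutes
in total.

# Known limitations

* Acceptance is property- and simulation-based: headline numbers of any
  real dataset (peak times, topographies, specific $t$ statistics) require
  that dataset and are out of scope.
* The forward-only and stimulus-locked controls are evaluated at
  caller-supplied peak times, mirroring the single-timepoint procedure;
  the package does not pick those peaks automatically.
* Frequency-resolved runs re-filter per band and re-use the same
  extrapolation with $f$ set to the band center; bands are rectangular
  (center ± 1 Hz by default) with no spectral taper.
* The logistic solver's convergence rules are the package's own policy;
  nothing is claimed about how any particular historical analysis handled
  separation or non-convergence.

```{r demo}
library(phasebind)
cfg <- sim_config(n_subjects = 6, n_trials = 120, n_channels = 4)
ds <- simulate_dataset(cfg, seed = 1)
subjects <- lapply(ds, function(su) {
  list(analytic = bandpass_analytic(su$epochs), trials = su$trials)
})
map <- predict_timecourse(subjects, times = seq(-1.9, 0, by = 0.1))
subset(map, significant)
```
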