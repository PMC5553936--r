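# phasebind

Statistical pipeline linking the phase of movement-locked theta (~4 Hz)
oscillations to trial-by-trial binary perceptual outcomes.

When observers prepare a timed voluntary movement, visual performance
fluctuates rhythmically in the theta range, locked to the upcoming movement.
phasebind provides, for researchers analyzing such paradigms (2AFC reports of
near-threshold stimuli presented around self-timed movements, with EEG):

* **Behavioral spectral tests** — per-subject circular-linear logistic
  regression of the outcome on `sin(2πf t)` and `cos(2πf t)` of the stimulus
  time `t` relative to movement onset, combined across subjects
  (random effects), and a fixed-effects FFT/permutation spectrum of the
  binned percent-correct time course.
* **EEG phase estimation** — two-pass 3–5 Hz Butterworth filtering, analytic
  signal (Hilbert), downsampling, and extrapolation of the measured phase to
  stimulus onset: `phase_at_stim = phase(t) + 2πf (t_stim − t)`.
* **Group-level inference on complex effects** — per-subject coefficient
  pairs `(β1, β2)` tested with Hotelling's `T² = n β̄' S⁻¹ β̄`
  (exact `F = (n−2)/(2(n−1)) T²` on `(2, n−2)` df), effect size
  `PV = ‖β̄‖` with jackknife SE, optimal phase `atan2(β̄1, β̄2)`,
  Benjamini–Hochberg FDR over channels × times, and label-permutation
  condition contrasts.
* **Phase-locking statistics** — mean resultant vectors / inter-trial
  coherence, inter-individual phase consistency, and the split-half complex
  spatial correlation `r(t)` across channels with a one-sample group t-test.
* **A ground-truth generator** — trial tables, force traces, and 1/f EEG with
  movement-locked theta bursts whose phase drives outcomes through the same
  logistic model the pipeline fits, so every stage is testable end to end
  without any external data.

## Worked example

The numbered drivers under `analysis/` run the whole workflow on synthetic
data and write tables under `results/`. The core analysis:

```sh
Rscript analysis/03_phase_predict.R
```

prints (seed fixed in the script):

```
simulated 17 subjects; late 4 Hz burst at -0.05 s, true optimal phase 1.047 rad
predictive value peaks at t = -0.05 s (PV = 0.94 +/- 0.08, p = 2.1e-08)
FDR-significant times span [-1.00, 0.00] s; recovered optimal phase 1.121 rad
forward-only control at t = -0.05 s: PV = 0.97 (vs 0.94) using >= 52 trials/subject
```

Reading: the generator placed a 4 Hz burst just before movement onset and
coupled outcomes to its phase with optimal phase π/3 ≈ 1.047 rad. The map
finds a group-significant predictive value peaking at the burst time, with
the recovered optimal phase within ~0.07 rad of the truth; significance
extends earlier than the raw burst because the zero-phase band-pass smears
phase information by a few hundred ms. The forward-only control (only trials
whose stimulus follows the phase-estimation point) reproduces the effect
from fewer trials. Similarly, `analysis/04_phase_locking.R` shows the
non-monotonic locking profile (mean Real r(t) ≈ 0.8 at both burst times
vs ≈ 0.1 in between), and `analysis/02_behavior_spectrum.R` recovers an
injected 4 Hz behavioral rhythm with both spectral methods.

## Package layout

* `R/` — the implementation (containers and IO, onset detection, simulator,
  analytic-signal chain, inference, behavioral spectra, phase-prediction
  map, phase locking).
* `analysis/01_simulate.R … 04_phase_locking.R` — narrative drivers writing
  `results/*.tsv`.
* `tests/testthat/` — unit, property and end-to-end statistical tests.
* `vignettes/movement-locked-phase.Rmd` — the methods vignette: model,
  assumptions, parameter rationale, numerical choices, limitations.
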