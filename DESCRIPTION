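Package: phasebind
Title: Movement-Locked Oscillatory Phase and Trial-by-Trial Perceptual Outcome
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical pipeline linking the phase of movement-locked theta
    (~4 Hz) oscillations to binary perceptual outcomes. Provides spectral tests
    of movement-aligned behavioral performance (random-effects circular-linear
    logistic regression and a fixed-effects FFT/permutation test), narrow-band
    analytic-signal phase estimation with forward/backward extrapolation to
    stimulus onset, group-level inference on complex-valued regression effects
    (Hotelling T-squared, jackknife standard errors, Benjamini-Hochberg FDR,
    permutation contrasts), movement-locked phase-alignment statistics (mean
    resultant vectors, inter-trial coherence, split-half complex spatial
    correlation), and a synthetic-data generator with known ground truth that
    exercises the full pipeline end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    rhdf5
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
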