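# phase_locking: MRVs, inter-individual consistency, split-half spatial correlation

test_that("mean resultant vectors follow the stated arithmetic", {
  # all trials at 1 + 0i
  ones <- analytic_from_array(array(1 + 0i, c(2, 3, 5)))
  expect_true(all(mrv(ones)$mrv == 1 + 0i))

  # antiphase trials cancel
  anti <- analytic_unit_phases(c(pi / 2, -pi / 2))
  expect_lt(max(Mod(mrv(anti)$mrv)), 1e-12)

  # amplitudes 2 and 4 at angle 0: mean 3 non-normalized, 1 normalized
  v <- array(0i, c(2, 3, 2))
  v[, , 1] <- 2 + 0i
  v[, , 2] <- 4 + 0i
  amp <- analytic_from_array(v)
  expect_true(all(Mod(mrv(amp)$mrv - 3) < 1e-12))
  expect_true(all(Mod(mrv(amp, normalized = TRUE)$mrv - 1) < 1e-12))

  expect_error(mrv(analytic_from_array(array(1 + 0i, c(2, 3, 1)))), "2 trials")
})

test_that("zero-amplitude samples are excluded from the normalized MRV", {
  v <- array(exp(1i * 0.3), c(2, 3, 4))
  v[1, 1, 1] <- 0i
  ae <- analytic_from_array(v)
  expect_warning(m <- mrv(ae, normalized = TRUE), "zero-amplitude")
  expect_equal(Mod(m$mrv[1, 1]), 1, tolerance = 1e-12) # mean of remaining unit vectors
  expect_false(any(m$undefined))

  # a cell where every trial is zero is undefined
  v[1, 1, ] <- 0i
  expect_warning(m2 <- mrv(analytic_from_array(v), normalized = TRUE), "zero-amplitude")
  expect_true(m2$undefined[1, 1])
  expect_true(is.na(m2$mrv[1, 1]))
})

test_that("normalized MRV equals the textbook inter-trial coherence", {
  set.seed(61)
  phases <- matrix(runif(3 * 40, -pi, pi), 40, 3) # trials x times, one channel pair
  amps <- matrix(rexp(3 * 40) + 0.1, 40, 3)
  v <- array(0i, c(2, 3, 40))
  for (i in 1:40) {
    v[, , i] <- matrix(amps[i, ] * exp(1i * phases[i, ]), 2, 3, byrow = TRUE)
  }
  m <- mrv(analytic_from_array(v), normalized = TRUE)
  # independent direct ITPC: |mean of unit phasors| from the phases alone
  itpc <- Mod(colMeans(exp(1i * phases)))
  expect_equal(Mod(m$mrv[1, ]), itpc, tolerance = 1e-12)
  expect_equal(Mod(m$mrv[2, ]), itpc, tolerance = 1e-12)
})

test_that("inter-individual consistency averages subjects' locked angles", {
  aligned <- lapply(1:5, function(s) mrv(analytic_unit_phases(rep(0, 6)), normalized = TRUE))
  g <- interindividual_consistency(aligned)
  expect_equal(max(abs(g$magnitude - 1)), 0, tolerance = 1e-12)

  opposite <- list(
    mrv(analytic_unit_phases(rep(0, 6)), normalized = TRUE),
    mrv(analytic_unit_phases(rep(pi, 6)), normalized = TRUE)
  )
  g2 <- interindividual_consistency(opposite)
  expect_lt(max(g2$magnitude), 1e-12)

  # random angles: group magnitude sits at the small-sample bias level
  set.seed(62)
  mags <- replicate(40, {
    maps <- lapply(1:17, function(s) {
      mrv(analytic_unit_phases(rep(runif(1, -pi, pi), 6), n_samples = 1),
        normalized = TRUE
      )
    })
    interindividual_consistency(maps)$magnitude[1, 1]
  })
  # E|mean of n unit phasors| ~= sqrt(pi)/2 / sqrt(n) for uniform angles
  expect_lt(abs(mean(mags) - sqrt(pi) / 2 / sqrt(17)), 0.06)

  short <- mrv(analytic_unit_phases(rep(0, 6), n_samples = 2), normalized = TRUE)
  expect_error(interindividual_consistency(list(aligned[[1]], short)), "grid")
})

test_that("the complex spatial correlation satisfies its exact identities", {
  set.seed(63)
  m1 <- matrix(complex(real = rnorm(20), imaginary = rnorm(20)), 4, 5)
  # self-correlation is exactly 1
  expect_equal(max(Mod(spatial_corr(m1, m1) - 1)), 0, tolerance = 1e-12)
  # rotated second half: r = e^{-i theta}, Real(r) = cos(theta)
  for (th in c(0.3, 1.2, -2.5)) {
    r <- spatial_corr(m1, m1 * exp(1i * th))
    expect_equal(max(Mod(r - exp(-1i * th))), 0, tolerance = 1e-12)
    expect_equal(Re(r), rep(cos(th), 5), tolerance = 1e-12)
  }
  # Cauchy-Schwarz bound holds for arbitrary pairs
  m2 <- matrix(complex(real = rnorm(20), imaginary = rnorm(20)), 4, 5)
  expect_true(all(Mod(spatial_corr(m1, m2)) <= 1 + 1e-12))
})

test_that("split-half correlation is exact for identical trials", {
  v <- array(0i, c(3, 4, 10))
  base <- matrix(complex(real = rnorm(12), imaginary = rnorm(12)), 3, 4)
  for (i in 1:10) v[, , i] <- base
  sh <- split_half_spatial_corr(analytic_from_array(v), n_partitions = 20, seed = 1)
  expect_equal(sh$real_r, rep(1, 4), tolerance = 1e-12)
})

test_that("split-half correlation is invariant to gain and channel order", {
  set.seed(64)
  v <- array(complex(real = rnorm(120), imaginary = rnorm(120)), c(3, 4, 10))
  ae <- analytic_from_array(v)
  base <- split_half_spatial_corr(ae, n_partitions = 50, seed = 2)

  gained <- ae
  gained$values <- 2.5 * gained$values
  expect_equal(
    split_half_spatial_corr(gained, n_partitions = 50, seed = 2)$real_r,
    base$real_r,
    tolerance = 1e-12
  )

  perm <- ae
  perm$values <- perm$values[c(3, 1, 2), , , drop = FALSE]
  expect_equal(
    split_half_spatial_corr(perm, n_partitions = 50, seed = 2)$real_r,
    base$real_r,
    tolerance = 1e-12
  )
})

test_that("odd trial counts drop one trial and still run", {
  set.seed(65)
  v <- array(complex(real = rnorm(135), imaginary = rnorm(135)), c(3, 5, 9))
  sh <- split_half_spatial_corr(analytic_from_array(v), n_partitions = 30, seed = 3)
  expect_length(sh$real_r, 5)
  expect_true(all(is.finite(sh$real_r)))
  expect_error(
    split_half_spatial_corr(analytic_from_array(v[1, , , drop = FALSE])),
    "2 channels"
  )
  expect_error(
    split_half_spatial_corr(analytic_from_array(v[, , 1:3])),
    "4 trials"
  )
})

test_that("split-half correlation centers on zero without phase locking", {
  set.seed(66)
  means <- replicate(150, {
    v <- array(complex(modulus = 1, argument = runif(4 * 3 * 12, -pi, pi)), c(4, 3, 12))
    mean(split_half_spatial_corr(analytic_from_array(v),
      n_partitions = 20,
      seed = sample.int(1e6, 1)
    )$real_r)
  })
  expect_lt(abs(mean(means)), 3 * sd(means) / sqrt(length(means)))
})

test_that("the group test flags locked epochs and spares silent ones", {
  # burst-locked oscillation at -1.4 s and -0.05 s with a quiet mid-interval;
  # noise is set high enough that the filter-smeared envelope tail (a few
  # percent of burst amplitude) stays below the per-half MRV noise floor
  # (~ noise * in-band fraction / sqrt(n_trials / 2)), so the dip is real
  cfg <- sim_config(
    n_subjects = 8, n_trials = 20, n_channels = 4, noise_amplitude = 4,
    theta_subject_sd = 0.5
  )
  ds <- simulate_dataset(cfg, seed = 67)
  times_keep <- NULL
  real_r <- t(vapply(ds, function(su) {
    ae <- bandpass_analytic(su$epochs, fs_out = 40)
    sh <- split_half_spatial_corr(ae, n_partitions = 40, seed = 68)
    times_keep <<- sh$time
    sh$real_r
  }, numeric(77)))
  g <- group_phase_locking_test(real_r, time = times_keep)
  sig_times <- g$time[g$significant]
  expect_true(any(abs(sig_times - (-1.4)) <= 0.15))
  expect_true(any(abs(sig_times - (-0.05)) <= 0.15))
  # non-monotonic profile: the zero-phase band-pass smears each burst by a
  # few hundred ms, so demand a pronounced dip between the bursts rather
  # than exact absence of locking there
  mid <- mean(g$mean_r[abs(g$time - (-0.725)) <= 0.1])
  at_burst <- c(
    g$mean_r[which.min(abs(g$time - (-1.4)))],
    g$mean_r[which.min(abs(g$time - (-0.05)))]
  )
  expect_lt(mid, 0.5 * min(at_burst))
})

test_that("degenerate inputs to the group test are handled", {
  zeros <- matrix(0, 5, 4)
  g <- group_phase_locking_test(zeros)
  expect_false(any(g$significant))
  expect_true(all(g$degenerate))
  expect_error(group_phase_locking_test(matrix(0, 2, 4)), "3 subjects")
})
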