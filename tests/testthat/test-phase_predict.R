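# phase_predict: extrapolation, logistic fits, the channel x time map, joint model

test_that("phase extrapolation satisfies the exact identities", {
  expect_equal(extrapolate_phase(pi / 2, 4, -0.1, -0.1), pi / 2) # zero lag
  expect_equal(extrapolate_phase(0, 4, -0.25, 0), 0) # one full period
  expect_equal(extrapolate_phase(0, 4, -0.5, -0.375), pi) # half period adds pi
  # backward extrapolation inverts forward extrapolation
  p <- extrapolate_phase(1.2, 4, -0.3, 0.2)
  expect_equal(extrapolate_phase(p, 4, 0.2, -0.3), 1.2)
  # output is wrapped to (-pi, pi]
  expect_true(all(abs(extrapolate_phase(runif(50, -pi, pi), 4, -1.9, 0.6)) <= pi))
})

test_that("the logistic fitter recovers known coefficients", {
  set.seed(51)
  ph <- runif(5000, -pi, pi)
  y <- simulate_outcomes(ph, 1.1, 0.8, pi / 3, seed = 52)
  fit <- fit_phase_outcome_model(ph, y)
  expect_true(fit$converged)
  expect_lt(abs(fit$beta1 - 0.6928), 3 * fit$se[2])
  expect_lt(abs(fit$beta2 - 0.4000), 3 * fit$se[3])
})

test_that("phase-independent outcomes give near-zero effects", {
  set.seed(53)
  ph <- runif(5000, -pi, pi)
  y <- rbinom(5000, 1, 0.75)
  fit <- fit_phase_outcome_model(ph, y)
  expect_lt(sqrt(fit$beta1^2 + fit$beta2^2), 0.1)
})

test_that("degenerate fits are flagged, not returned as converged", {
  ph <- runif(200, -pi, pi)
  # perfect separation in the cosine direction
  sep <- fit_phase_outcome_model(ph, as.integer(cos(ph) > 0))
  expect_false(sep$converged)
  expect_true(is.na(sep$beta1))
  # single outcome class
  one <- fit_phase_outcome_model(ph, rep(1L, 200))
  expect_false(one$converged)
  # too few trials
  few <- fit_phase_outcome_model(ph[1:10], rbinom(10, 1, 0.5))
  expect_false(few$converged)
})

test_that("the IRLS fit agrees with the independent grid-search ML oracle", {
  set.seed(54)
  for (k in 1:3) {
    ph <- runif(800, -pi, pi)
    y <- simulate_outcomes(ph, 0.5, 0.6, runif(1, -pi, pi), seed = 54 + k)
    fit <- fit_phase_outcome_model(ph, y)
    ora <- fit_phase_outcome_grid(ph, y)
    expect_lt(max(abs(c(
      fit$beta0 - ora$beta0, fit$beta1 - ora$beta1, fit$beta2 - ora$beta2
    ))), 1e-3)
  }
})

test_that("the predictive-value map localizes a late-burst effect", {
  cfg <- sim_config(
    n_subjects = 6, n_trials = 120, n_channels = 2, noise_amplitude = 0.4,
    bursts = list(list(center = -0.05, width = 0.15, amplitude = 1)),
    couple_burst = 1, theta_subject_sd = 0.3, kappa = 1
  )
  ds <- simulate_dataset(cfg, seed = 55)
  subjects <- lapply(ds, function(su) {
    list(analytic = bandpass_analytic(su$epochs), trials = su$trials)
  })
  map <- predict_timecourse(subjects, times = c(-1.4, -0.6, -0.1))
  expect_s3_class(map, "phase_predict_map")
  late <- map[map$time == -0.1, ]
  early <- map[map$time == -1.4, ]
  expect_lt(min(late$p), 0.01)
  expect_gt(max(late$pv), max(early$pv))
  expect_lt(abs(wrap_phase(late$phi_opt[which.max(late$pv)] - pi / 3)), 0.4)

  # channel relabeling permutes the map identically
  perm <- c(2, 1)
  subjects_p <- lapply(subjects, function(su) {
    a <- su$analytic
    a$values <- a$values[perm, , , drop = FALSE]
    a$channel_labels <- a$channel_labels[perm]
    list(analytic = a, trials = su$trials)
  })
  map_p <- predict_timecourse(subjects_p, times = c(-1.4, -0.6, -0.1))
  key <- paste(map$channel, map$time)
  key_p <- paste(map_p$channel, map_p$time)
  expect_equal(map_p$pv[match(key, key_p)], map$pv)

  # reproducibility: identical inputs give an identical map
  expect_identical(predict_timecourse(subjects, times = c(-1.4, -0.6, -0.1)), map)
})

test_that("forward-only cells use fewer trials but agree at high SNR", {
  cfg <- sim_config(
    n_subjects = 6, n_trials = 160, n_channels = 2, noise_amplitude = 0.25,
    bursts = list(list(center = -0.1, width = 0.2, amplitude = 1)),
    couple_burst = 1, theta_subject_sd = 0.2, kappa = 1
  )
  ds <- simulate_dataset(cfg, seed = 56)
  subjects <- lapply(ds, function(su) {
    list(analytic = bandpass_analytic(su$epochs), trials = su$trials)
  })
  all_map <- predict_timecourse(subjects, times = -0.1)
  fwd_map <- predict_timecourse(subjects, times = -0.1, variant = "forward_only")
  expect_true(all(fwd_map$n_trials_min < all_map$n_trials_min))
  expect_equal(attr(all_map, "fdr_family"), "space")
  # same effect within a jackknife SE at high SNR
  expect_lt(
    abs(fwd_map$pv[1] - all_map$pv[1]),
    fwd_map$se[1] + all_map$se[1]
  )
})

test_that("stimulus-locked variant reads phases without extrapolation", {
  set.seed(57)
  # stimulus-aligned analytic data whose phase at t = -0.1 drives the outcome
  n_tr <- 200
  subjects <- lapply(1:8, function(s) {
    phases <- runif(n_tr, -pi, pi)
    v <- array(0i, dim = c(2, 381, n_tr))
    tgrid <- seq(-1.9, 0, by = 0.005)
    for (i in seq_len(n_tr)) {
      v[, , i] <- matrix(exp(1i * (phases[i] + 2 * pi * 4 * (tgrid + 0.1))),
        2, 381,
        byrow = TRUE
      )
    }
    ae <- analytic_epochs(v, 200, tgrid, 4, c(3, 5))
    y <- simulate_outcomes(phases, 1.1, 1, 0, seed = 570 + s)
    tt <- quick_trials(runif(n_tr, -0.35, 0.25), y)
    list(analytic = ae, trials = tt)
  })
  map <- predict_timecourse(subjects, times = -0.1, variant = "stimulus_locked")
  expect_lt(min(map$p), 0.01)
  expect_lt(abs(wrap_phase(map$phi_opt[which.max(map$pv)])), 0.25)
  # pre-movement restriction drops trials with t_stim >= 0
  pre <- predict_timecourse(subjects,
    times = -0.1, variant = "stimulus_locked",
    pre_movement_only = TRUE
  )
  expect_true(all(pre$n_trials_min < map$n_trials_min))
})

test_that("cells failing the minimum-trial rule are masked", {
  set.seed(58)
  v <- array(complex(modulus = 1, argument = runif(2 * 381 * 20, -pi, pi)),
    dim = c(2, 381, 20)
  )
  ae <- analytic_epochs(v, 200, seq(-1.9, 0, by = 0.005), 4, c(3, 5))
  tt <- quick_trials(runif(20, -0.5, 0.5), rbinom(20, 1, 0.75))
  subjects <- lapply(1:4, function(s) list(analytic = ae, trials = tt))
  map <- predict_timecourse(subjects, times = -0.1, min_trials = 30)
  expect_false(any(map$ok))
  expect_true(all(is.na(map$p)))
  expect_false(any(map$significant))
})

test_that("the joint early/late model partials the two phase effects", {
  set.seed(59)
  n <- 5000
  ph_e <- runif(n, -pi, pi)
  ph_l <- runif(n, -pi, pi)
  p <- plogis(1 + 0.5 * cos(ph_e - pi / 4) + 0.5 * cos(ph_l + 2))
  y <- rbinom(n, 1, p)
  fit <- joint_early_late_model(ph_e, ph_l, y)
  expect_true(fit$converged)
  expect_lt(abs(wrap_phase(atan2(fit$early[1], fit$early[2]) - pi / 4)), 0.3)
  expect_lt(abs(wrap_phase(atan2(fit$late[1], fit$late[2]) - (-2))), 0.3)

  # fully coupled phases: joint fit flagged, single-predictor fits remain valid
  col <- joint_early_late_model(ph_e, ph_e + 0.5, y)
  expect_true(col$collinear)
  expect_false(col$converged)
  single <- fit_phase_outcome_model(ph_e, y)
  expect_true(single$converged)

  # outcome coupled only to the early phase: late effect near zero
  y2 <- rbinom(n, 1, plogis(1 + 0.6 * cos(ph_e)))
  fit2 <- joint_early_late_model(ph_e, ph_l, y2)
  expect_gt(sqrt(sum(fit2$early^2)), 0.4)
  expect_lt(sqrt(sum(fit2$late^2)), 0.15)
})

test_that("group-level joint test summarizes both partialled effects", {
  set.seed(60)
  fits <- lapply(1:8, function(s) {
    n <- 1200
    ph_e <- runif(n, -pi, pi)
    ph_l <- runif(n, -pi, pi)
    y <- rbinom(n, 1, plogis(1 + 0.5 * cos(ph_e - pi / 4) + 0.5 * cos(ph_l + 2)))
    joint_early_late_model(ph_e, ph_l, y)
  })
  g <- joint_group_test(fits)
  expect_lt(g$early$p, 0.01)
  expect_lt(g$late$p, 0.01)
  expect_lt(abs(wrap_phase(g$early$phi_opt - pi / 4)), 0.3)
  expect_lt(abs(wrap_phase(g$late$phi_opt - (-2))), 0.3)
})
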