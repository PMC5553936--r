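#' Extrapolate a measured phase to stimulus onset
#'
#' Assuming constant frequency `f`, the phase measured at time `t` is
#' projected to the stimulus time:
#' `phase_at_stim = phase + 2 pi f (t_stim - t)`, wrapped to `(-pi, pi]`.
#' Works forward (`t_stim > t`) and backward (`t_stim < t`) in time.
#'
#' @param phase measured phase(s) at `t`, radians.
#' @param f assumed frequency, Hz.
#' @param t phase-estimation time, seconds.
#' @param t_stim stimulus time, seconds (same reference as `t`).
#' @return extrapolated phase(s), wrapped to `(-pi, pi]`.
#' @export
#' @examples
#' extrapolate_phase(0, f = 4, t = -0.25, t_stim = 0) # one full period: 0
#' extrapolate_phase(0, f = 4, t = -0.5, t_stim = -0.375) # half period: pi
extrapolate_phase <- function(phase, f, t, t_stim) {
  stopifnot(all(is.finite(c(phase, f, t, t_stim))))
  wrap_phase(phase + 2 * pi * f * (t_stim - t))
}

#' Fit the phase-outcome logistic regression for one subject
#'
#' Maximum-likelihood fit of
#' `P(correct) = plogis(b0 + b1 sin(phase) + b2 cos(phase))`. Fits with
#' fewer than `min_trials` trials, with a single outcome class, or showing
#' symptoms of separation (fitted probabilities pinned at 0/1, or runaway
#' coefficients) are flagged `converged = FALSE` and carry NA coefficients.
#'
#' @param phase_at_stim per-trial phases, radians.
#' @param outcomes per-trial 0/1 outcomes.
#' @param min_trials minimum trial count (default 30).
#' @return list of class `subject_betas`: `beta0`, `beta1` (sine), `beta2`
#'   (cosine), `n`, `converged`.
#' @export
fit_phase_outcome_model <- function(phase_at_stim, outcomes, min_trials = 30) {
  n <- length(outcomes)
  bad <- function() {
    structure(
      list(
        beta0 = NA_real_, beta1 = NA_real_, beta2 = NA_real_,
        n = n, converged = FALSE
      ),
      class = "subject_betas"
    )
  }
  if (n != length(phase_at_stim)) stop("phase and outcome lengths differ")
  if (n < min_trials || length(unique(outcomes)) < 2) {
    return(bad())
  }
  s <- sin(phase_at_stim)
  co <- cos(phase_at_stim)
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm(outcomes ~ s + co, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        separated <<- TRUE
      }
      invokeRestart("muffleWarning")
    }
  )
  cf <- stats::coef(fit)
  if (separated || !fit$converged || any(!is.finite(cf)) || max(abs(cf)) > 15) {
    return(bad())
  }
  structure(
    list(
      beta0 = unname(cf[1]), beta1 = unname(cf[2]), beta2 = unname(cf[3]),
      n = n, converged = TRUE, se = sqrt(diag(stats::vcov(fit)))
    ),
    class = "subject_betas"
  )
}

#' Reference fitter: direct likelihood maximization on a grid
#'
#' Brute-force maximum-likelihood fit of the same model as
#' [fit_phase_outcome_model()], by coarse grid search over
#' `(b0, kappa, phi_opt)` (with `b1 = kappa sin(phi_opt)`,
#' `b2 = kappa cos(phi_opt)`) followed by Nelder-Mead refinement of the
#' exact binomial log-likelihood. Shares no code path with the IRLS route,
#' so it serves as an independent cross-check.
#'
#' @inheritParams fit_phase_outcome_model
#' @return list with `beta0`, `beta1`, `beta2`, `loglik`.
#' @export
fit_phase_outcome_grid <- function(phase_at_stim, outcomes) {
  s <- sin(phase_at_stim)
  co <- cos(phase_at_stim)
  y <- outcomes
  nll <- function(par) {
    eta <- par[1] + par[2] * s + par[3] * co
    # -sum(y*eta - log(1 + exp(eta))), numerically stable form
    sum((1 - y) * eta + log1p(exp(-eta)))
  }
  best <- NULL
  best_v <- Inf
  for (b0 in seq(-2, 2, by = 0.5)) {
    for (kap in seq(0, 2, by = 0.25)) {
      for (phi in seq(-pi, pi, length.out = 17)[-17]) {
        par <- c(b0, kap * sin(phi), kap * cos(phi))
        v <- nll(par)
        if (v < best_v) {
          best_v <- v
          best <- par
        }
      }
    }
  }
  opt <- stats::optim(best, nll,
    method = "Nelder-Mead",
    control = list(reltol = 1e-14, maxit = 5000)
  )
  opt <- stats::optim(opt$par, nll,
    method = "Nelder-Mead",
    control = list(reltol = 1e-14, maxit = 5000)
  )
  list(
    beta0 = opt$par[1], beta1 = opt$par[2], beta2 = opt$par[3],
    loglik = -opt$value
  )
}

# phases of one subject's analytic values at one sample index: ch x trials
phases_at_index <- function(analytic, idx, trial_cols) {
  v <- analytic$values[, idx, trial_cols, drop = FALSE]
  Arg(array(v, dim = dim(v)[c(1, 3)]))
}

#' Group-level predictive-value map over channels and time
#'
#' The core analysis: for every channel and phase-estimation time `t` (default
#' -1.9 to 0 s in steps of 0.025 s), each subject's measured phases at `t`
#' are extrapolated to the per-trial stimulus times ([extrapolate_phase()]
#' at the band's center frequency) and regressed on the binary outcome
#' ([fit_phase_outcome_model()]); the subject-level `(b1, b2)` pairs are then
#' combined with [hotelling_t2()], [predictive_value()] and [jackknife_se()].
#' The BH-FDR mask is computed across the full space x time family (or across
#' space only when a single time is analyzed, as for the single-timepoint
#' control variants).
#'
#' Variants: `"all_trials"` uses every trial in the +/-0.6 s analysis window;
#' `"forward_only"` keeps, at each time `t`, only trials with `t_stim > t`
#' (forward extrapolation, immune to stimulus-evoked activity);
#' `"stimulus_locked"` consumes stimulus-aligned epochs and uses the measured
#' phase at `t` directly, without extrapolation (restrict trials with
#' `pre_movement_only` for the pre-movement control).
#'
#' @param subjects list of per-subject lists, each with elements `analytic`
#'   (an [analytic_epochs()]) and `trials` (a [trial_table()] whose rows
#'   match the trial dimension of the analytic array).
#' @param times phase-estimation times, seconds (matched to the nearest
#'   analytic sample).
#' @param variant `"all_trials"`, `"forward_only"` or `"stimulus_locked"`.
#' @param f extrapolation frequency; default the analytic center frequency.
#' @param min_trials minimum trials per subject and cell (default 30; cells
#'   with fewer converged subjects than `min_subjects` are masked).
#' @param min_subjects minimum converged subjects per cell.
#' @param q FDR level.
#' @param pre_movement_only for `"stimulus_locked"`: keep only trials with
#'   the stimulus before movement onset.
#' @return data.frame of class `phase_predict_map`, one row per channel x
#'   time: `channel`, `time`, `pv`, `se`, `t2`, `p`, `phi_opt`,
#'   `n_subjects`, `n_trials_min`, `ok`, `significant`.
#' @export
predict_timecourse <- function(subjects, times = seq(-1.9, 0, by = 0.025),
                               variant = c("all_trials", "forward_only", "stimulus_locked"),
                               f = NULL, min_trials = 30, min_subjects = 3,
                               q = 0.05, pre_movement_only = FALSE) {
  variant <- match.arg(variant)
  a1 <- subjects[[1]]$analytic
  if (is.null(f)) f <- a1$center_freq
  nch <- dim(a1$values)[1]
  # per subject: analysis-window trial mask mapped onto analytic trial columns
  prep <- lapply(subjects, function(su) {
    tt <- su$trials
    keep <- abs(tt$t_stim) <= 0.6
    if (variant == "stimulus_locked" && pre_movement_only) keep <- keep & tt$t_stim < 0
    list(
      analytic = su$analytic, cols = which(keep),
      t_stim = tt$t_stim[keep], outcome = tt$outcome[keep]
    )
  })
  rows <- list()
  for (t in times) {
    idx <- which.min(abs(a1$time - t))
    if (abs(a1$time[idx] - t) > 0.5 / a1$fs_out + 1e-9) {
      stop("requested time ", t, " s is not on the analytic sample grid")
    }
    per_subj_phases <- lapply(prep, function(p) phases_at_index(p$analytic, idx, p$cols))
    for (ch in seq_len(nch)) {
      fits <- lapply(seq_along(prep), function(s) {
        p <- prep[[s]]
        ph <- per_subj_phases[[s]][ch, ]
        sel <- if (variant == "forward_only") p$t_stim > t else rep(TRUE, length(p$t_stim))
        ph <- ph[sel]
        ts <- p$t_stim[sel]
        y <- p$outcome[sel]
        pas <- if (variant == "stimulus_locked") ph else extrapolate_phase(ph, f, t, ts)
        fit <- fit_phase_outcome_model(pas, y, min_trials = min_trials)
        fit$n_used <- length(y)
        fit
      })
      conv <- vapply(fits, function(x) isTRUE(x$converged), logical(1))
      nmin <- min(vapply(fits, function(x) x$n_used, numeric(1)))
      if (sum(conv) >= min_subjects) {
        b <- do.call(rbind, lapply(fits[conv], function(x) c(x$beta1, x$beta2)))
        ht <- hotelling_t2(b)
        pv <- predictive_value(b)
        rows[[length(rows) + 1]] <- data.frame(
          channel = a1$channel_labels[ch], time = t, pv = pv$pv,
          se = jackknife_se(b), t2 = ht$t2, p = ht$p, phi_opt = pv$phi_opt,
          n_subjects = sum(conv), n_trials_min = nmin, ok = TRUE
        )
      } else {
        rows[[length(rows) + 1]] <- data.frame(
          channel = a1$channel_labels[ch], time = t, pv = NA_real_,
          se = NA_real_, t2 = NA_real_, p = NA_real_, phi_opt = NA_real_,
          n_subjects = sum(conv), n_trials_min = nmin, ok = FALSE
        )
      }
    }
  }
  map <- do.call(rbind, rows)
  map$significant <- fdr_bh(map$p, q)
  attr(map, "variant") <- variant
  attr(map, "f") <- f
  attr(map, "fdr_family") <- if (length(times) > 1) "space_x_time" else "space"
  class(map) <- c("phase_predict_map", "data.frame")
  map
}

#' Joint logistic model with early and late phase predictors
#'
#' One logistic fit with four phase regressors — sine and cosine of the
#' early-epoch phase and of the late-epoch phase — so each pair is partialled
#' on the other. Near-perfect collinearity between the two phases (e.g. late
#' = early + constant) is detected from the regressor cross-correlation and
#' flagged; the joint fit is then invalid while single-predictor fits remain
#' usable.
#'
#' @param phase_early,phase_late per-trial phases (rad) for the same trials.
#' @param outcomes per-trial 0/1 outcomes.
#' @param min_trials minimum trial count.
#' @return list with `early` and `late` (each `c(beta1, beta2)`), `beta0`,
#'   `converged`, `collinear`, `n`.
#' @export
joint_early_late_model <- function(phase_early, phase_late, outcomes, min_trials = 30) {
  n <- length(outcomes)
  stopifnot(length(phase_early) == n, length(phase_late) == n)
  bad <- function(collinear = FALSE) {
    list(
      early = c(NA_real_, NA_real_), late = c(NA_real_, NA_real_),
      beta0 = NA_real_, converged = FALSE, collinear = collinear, n = n
    )
  }
  if (n < min_trials || length(unique(outcomes)) < 2) {
    return(bad())
  }
  X <- cbind(sin(phase_early), cos(phase_early), sin(phase_late), cos(phase_late))
  # rank-deficient or nearly collinear phase pairs make the joint fit unstable
  if (qr(cbind(1, X))$rank < 5 ||
    max(abs(stats::cor(X[, 1:2], X[, 3:4]))) > 0.995) {
    return(bad(collinear = TRUE))
  }
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm(outcomes ~ X, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        separated <<- TRUE
      }
      invokeRestart("muffleWarning")
    }
  )
  cf <- stats::coef(fit)
  if (separated || !fit$converged || any(!is.finite(cf)) || max(abs(cf)) > 15) {
    return(bad())
  }
  list(
    early = unname(cf[2:3]), late = unname(cf[4:5]), beta0 = unname(cf[1]),
    converged = TRUE, collinear = FALSE, n = n
  )
}

#' Group-level test of the joint early/late effects
#'
#' Applies [hotelling_t2()] and [predictive_value()] separately to the
#' partialled early and late coefficient pairs of per-subject
#' [joint_early_late_model()] fits.
#'
#' @param fits list of joint fits (non-converged fits are dropped).
#' @return list with elements `early` and `late`, each carrying `t2`, `p`,
#'   `pv`, `se`, `phi_opt`, `n`.
#' @export
joint_group_test <- function(fits) {
  conv <- vapply(fits, function(x) isTRUE(x$converged), logical(1))
  if (sum(conv) < 3) stop("fewer than 3 converged joint fits")
  summarize <- function(which) {
    b <- do.call(rbind, lapply(fits[conv], function(x) x[[which]]))
    ht <- hotelling_t2(b)
    pv <- predictive_value(b)
    list(
      t2 = ht$t2, p = ht$p, pv = pv$pv, se = jackknife_se(b),
      phi_opt = pv$phi_opt, n = nrow(b)
    )
  }
  list(early = summarize("early"), late = summarize("late"))
}
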