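#' Hotelling T-squared test of a bivariate mean against zero
#'
#' `T2 = n * m' S^{-1} m` with `m` the sample mean of the n x 2 coefficient
#' matrix and `S` its sample covariance (n - 1 denominator). The p-value uses
#' the exact F transformation `F = ((n - 2) / (2 (n - 1))) * T2` on (2, n - 2)
#' degrees of freedom. When the sample mean is exactly zero the statistic is 0
#' and p = 1 regardless of `S`; otherwise a singular covariance is an error.
#'
#' @param betas numeric n x 2 matrix (n >= 3), one (sine, cosine) coefficient
#'   pair per subject; a complex vector is accepted as `Re` = sine, `Im` =
#'   cosine.
#' @return list with `t2`, `p`, `n`, `mean` and `cov`.
#' @export
hotelling_t2 <- function(betas) {
  betas <- as_beta_matrix(betas)
  n <- nrow(betas)
  if (n < 3) stop("hotelling_t2 requires at least 3 subjects")
  if (any(!is.finite(betas))) stop("betas must be finite")
  m <- colMeans(betas)
  S <- stats::cov(betas)
  if (all(m == 0)) {
    return(list(t2 = 0, p = 1, n = n, mean = m, cov = S))
  }
  Sinv <- tryCatch(solve(S), error = function(e) {
    stop("sample covariance of the betas is singular (zero variance?)")
  })
  if (rcond_2x2(S) < 1e-12) {
    stop("sample covariance of the betas is singular (zero variance?)")
  }
  t2 <- drop(n * t(m) %*% Sinv %*% m)
  f <- (n - 2) / (2 * (n - 1)) * t2
  list(t2 = t2, p = stats::pf(f, 2, n - 2, lower.tail = FALSE), n = n, mean = m, cov = S)
}

rcond_2x2 <- function(S) {
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (max(ev) <= 0) 0 else max(min(ev), 0) / max(ev)
}

as_beta_matrix <- function(betas) {
  if (is.complex(betas)) betas <- cbind(Re(betas), Im(betas))
  betas <- as.matrix(betas)
  if (ncol(betas) != 2) stop("betas must be an n x 2 matrix (sine, cosine)")
  betas
}

#' Predictive value and optimal phase of group-mean coefficients
#'
#' The predictive value is the Euclidean norm of the sample mean
#' coefficient pair, `PV = sqrt(mean(b1)^2 + mean(b2)^2)` with `b1` the sine
#' and `b2` the cosine coefficient. The optimal phase — the phase maximizing
#' `mean(b1) sin(phi) + mean(b2) cos(phi)`, i.e. the phase of highest
#' predicted performance — is `atan2(mean(b1), mean(b2))`. Both are invariant
#' (PV) / equivariant (phase) under a common rotation of all subjects'
#' complex effects.
#'
#' @inheritParams hotelling_t2
#' @return list with `pv`, `phi_opt` (NA with `defined = FALSE` when PV = 0)
#'   and `mean`.
#' @export
predictive_value <- function(betas) {
  betas <- as_beta_matrix(betas)
  m <- colMeans(betas)
  pv <- sqrt(sum(m^2))
  if (pv == 0) {
    list(pv = 0, phi_opt = NA_real_, defined = FALSE, mean = m)
  } else {
    list(pv = pv, phi_opt = atan2(m[1], m[2]), defined = TRUE, mean = m)
  }
}

#' Jackknife standard error of a group-level estimator
#'
#' Leave-one-subject-out resampling:
#' `SE = sqrt((n - 1) / n * sum((est_i - mean(est))^2))` over the n
#' leave-one-out estimates.
#'
#' @param betas n x 2 matrix (or any object subsettable by row index via
#'   `[`), n >= 2.
#' @param estimator function mapping the subsetted data to a scalar; default
#'   the predictive value.
#' @return the jackknife SE (scalar).
#' @export
jackknife_se <- function(betas, estimator = function(b) predictive_value(b)$pv) {
  if (is.complex(betas)) betas <- cbind(Re(betas), Im(betas))
  n <- if (is.matrix(betas) || is.data.frame(betas)) nrow(betas) else length(betas)
  if (n < 2) stop("jackknife requires at least 2 subjects")
  loo <- vapply(seq_len(n), function(i) {
    sub <- if (is.matrix(betas) || is.data.frame(betas)) {
      betas[-i, , drop = FALSE]
    } else {
      betas[-i]
    }
    estimator(sub)
  }, numeric(1))
  sqrt((n - 1) / n * sum((loo - mean(loo))^2))
}

#' Benjamini-Hochberg FDR rejection mask
#'
#' Step-up procedure over the supplied p-value family (the caller assembles
#' the space x time, space-only or time-only family). NA p-values are never
#' rejected.
#'
#' @param pvals numeric vector of p-values in \[0, 1\] (NAs allowed).
#' @param q FDR level.
#' @return logical rejection mask, same length as `pvals`.
#' @export
fdr_bh <- function(pvals, q = 0.05) {
  if (length(pvals) == 0) {
    return(logical(0))
  }
  ok <- !is.na(pvals)
  if (any(pvals[ok] < 0 | pvals[ok] > 1)) stop("p-values must lie in [0, 1]")
  mask <- logical(length(pvals))
  mask[ok] <- stats::p.adjust(pvals[ok], method = "BH") <= q
  mask
}

#' Permutation test for a condition difference in predictive value
#'
#' Statistic: `|PV_short - PV_long|`. The null distribution is built by
#' independently swapping each subject's condition labels (its matched pair
#' of complex effects) per permutation. The p-value counts permutations with
#' a statistic `>=` the observed one, with the add-one correction, so the
#' minimum attainable p is `1 / (n_perm + 1)`.
#'
#' @param betas_short,betas_long matched n x 2 coefficient matrices (or
#'   complex vectors), one row per subject.
#' @param n_perm number of permutations (>= 1).
#' @param seed integer seed.
#' @return list with `p`, `observed` and `null` (the permutation statistics).
#' @export
permute_condition_difference <- function(betas_short, betas_long, n_perm = 1000, seed = 1) {
  bs <- as_beta_matrix(betas_short)
  bl <- as_beta_matrix(betas_long)
  if (nrow(bs) != nrow(bl)) stop("conditions must have matched subjects")
  if (n_perm < 1) stop("n_perm must be >= 1")
  n <- nrow(bs)
  obs <- abs(predictive_value(bs)$pv - predictive_value(bl)$pv)
  set.seed(seed)
  null <- vapply(seq_len(n_perm), function(k) {
    swap <- stats::rbinom(n, 1, 0.5) == 1
    s <- bs
    l <- bl
    s[swap, ] <- bl[swap, ]
    l[swap, ] <- bs[swap, ]
    abs(predictive_value(s)$pv - predictive_value(l)$pv)
  }, numeric(1))
  list(p = (1 + sum(null >= obs)) / (n_perm + 1), observed = obs, null = null)
}
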