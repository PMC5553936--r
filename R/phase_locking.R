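#' Mean resultant vectors of the analytic signal
#'
#' The per-channel, per-time mean across trials of the complex analytic
#' signal. With `normalized = TRUE` each trial's value is first scaled to
#' unit modulus (`H / |H|`), giving the amplitude-normalized MRV, i.e. the
#' inter-trial coherence; zero-amplitude samples are excluded from the
#' normalized mean with a warning.
#'
#' @param analytic an [analytic_epochs()] with at least 2 trials.
#' @param normalized logical.
#' @return list of class `mrv_map`: `mrv` (complex channels x time matrix),
#'   `time`, `normalized`, `n_trials`, `undefined` (logical matrix marking
#'   cells where every trial had zero amplitude).
#' @export
mrv <- function(analytic, normalized = FALSE) {
  v <- analytic$values
  if (dim(v)[3] < 2) stop("mrv requires at least 2 trials")
  undefined <- matrix(FALSE, dim(v)[1], dim(v)[2])
  if (normalized) {
    a <- Mod(v)
    zero <- a == 0
    if (any(zero)) {
      warning("zero-amplitude samples excluded from the normalized MRV")
      v[zero] <- NA_complex_
      a[zero] <- 1
    }
    v <- v / a
    undefined <- apply(zero, c(1, 2), all)
  }
  m <- apply(v, c(1, 2), function(x) mean(x[!is.na(x)]))
  m[undefined] <- NA_complex_
  structure(
    list(
      mrv = m, time = analytic$time, normalized = normalized,
      n_trials = dim(analytic$values)[3], undefined = undefined,
      channel_labels = analytic$channel_labels
    ),
    class = "mrv_map"
  )
}

#' Inter-individual consistency of movement-locked phases
#'
#' Averages subjects' amplitude-normalized MRV maps; the magnitude of the
#' complex group mean is high only where subjects share the locked phase
#' angle.
#'
#' @param mrv_maps list of normalized [mrv()] maps on a common
#'   channel/time grid.
#' @return list with `mean` (complex group-mean map), `magnitude` and
#'   `angle` matrices, `n_subjects`.
#' @export
interindividual_consistency <- function(mrv_maps) {
  stopifnot(length(mrv_maps) >= 1)
  ref <- mrv_maps[[1]]
  for (m in mrv_maps) {
    if (!isTRUE(all.equal(dim(m$mrv), dim(ref$mrv))) ||
      max(abs(m$time - ref$time)) > 1e-9) {
      stop("MRV maps are not on a common channel/time grid")
    }
    if (!m$normalized) stop("interindividual_consistency expects normalized MRVs")
  }
  g <- Reduce(`+`, lapply(mrv_maps, function(m) m$mrv)) / length(mrv_maps)
  list(
    mean = g, magnitude = Mod(g), angle = Arg(g),
    n_subjects = length(mrv_maps), time = ref$time
  )
}

#' Complex spatial correlation between two MRV vectors
#'
#' `r = <m1, conj(m2)> / (||m1|| ||m2||)` across channels, per time point
#' (columns). By Cauchy-Schwarz `|r| <= 1`; under genuine movement-locked
#' phase alignment the two halves share phases, so `Real(r)` is positive,
#' while under the no-locking null its expectation is 0.
#'
#' @param m1,m2 complex channels x time matrices.
#' @return complex vector of correlations, one per time point.
#' @export
spatial_corr <- function(m1, m2) {
  stopifnot(all(dim(m1) == dim(m2)), nrow(m1) >= 2)
  num <- colSums(m1 * Conj(m2))
  den <- sqrt(colSums(Mod(m1)^2) * colSums(Mod(m2)^2))
  num / den
}

#' Split-half spatial correlation of movement-locked MRVs (one subject)
#'
#' For each of `n_partitions` random partitions, the trials are split into
#' two halves of equal size (with an odd trial count, one trial is dropped
#' uniformly at random), the complex MRV map is computed per half, and the
#' two maps are correlated across channels at each time point with
#' [spatial_corr()]. The real parts are averaged over partitions (the complex
#' mean is also returned for diagnostics).
#'
#' @param analytic an [analytic_epochs()] with >= 4 trials and >= 2 channels.
#' @param n_partitions number of random partitions (default 500).
#' @param seed integer seed.
#' @return list of class `split_half`: `time`, `real_r` (partition-mean of
#'   `Real(r(t))`), `complex_r`, `n_partitions`, `n_trials`.
#' @export
split_half_spatial_corr <- function(analytic, n_partitions = 500, seed = 1) {
  v <- analytic$values
  d <- dim(v)
  if (d[1] < 2) stop("split-half spatial correlation requires >= 2 channels")
  if (d[3] < 4) stop("split-half spatial correlation requires >= 4 trials")
  nt <- d[3]
  half <- nt %/% 2
  V <- matrix(v, d[1] * d[2], nt) # flatten channel x time for fast trial means
  set.seed(seed)
  acc_re <- numeric(d[2])
  acc_c <- complex(length.out = d[2])
  for (p in seq_len(n_partitions)) {
    ord <- sample.int(nt)
    h1 <- ord[1:half]
    h2 <- ord[(half + 1):(2 * half)]
    m1 <- matrix(rowMeans(V[, h1, drop = FALSE]), d[1], d[2])
    m2 <- matrix(rowMeans(V[, h2, drop = FALSE]), d[1], d[2])
    r <- spatial_corr(m1, m2)
    acc_re <- acc_re + Re(r)
    acc_c <- acc_c + r
  }
  structure(
    list(
      time = analytic$time, real_r = acc_re / n_partitions,
      complex_r = acc_c / n_partitions, n_partitions = n_partitions,
      n_trials = nt
    ),
    class = "split_half"
  )
}

#' Group test of movement-locked phase alignment
#'
#' One-sample t-test, per time point, of the subjects' partition-averaged
#' `Real(r(t))` against 0, with a BH-FDR mask across time points. Time points
#' with zero variance across subjects yield a degenerate t and are flagged
#' (`NA` p, never rejected) unless the mean is also zero.
#'
#' @param real_r numeric subjects x time matrix of partition-averaged
#'   `Real(r(t))` values (>= 3 subjects).
#' @param time optional time axis for the output.
#' @param q FDR level.
#' @return data.frame with `time` (or column index), `mean_r`, `t`, `p`,
#'   `significant`, `degenerate`.
#' @export
group_phase_locking_test <- function(real_r, time = NULL, q = 0.05) {
  real_r <- as.matrix(real_r)
  if (nrow(real_r) < 3) stop("group test requires >= 3 subjects")
  nt <- ncol(real_r)
  tstat <- rep(NA_real_, nt)
  p <- rep(NA_real_, nt)
  degen <- logical(nt)
  for (k in seq_len(nt)) {
    x <- real_r[, k]
    if (stats::sd(x) == 0) {
      degen[k] <- TRUE
      tstat[k] <- if (mean(x) == 0) 0 else Inf
    } else {
      tt <- stats::t.test(x, mu = 0)
      tstat[k] <- unname(tt$statistic)
      p[k] <- tt$p.value
    }
  }
  data.frame(
    time = if (is.null(time)) seq_len(nt) else time,
    mean_r = colMeans(real_r), t = tstat, p = p,
    significant = fdr_bh(p, q), degenerate = degen
  )
}
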