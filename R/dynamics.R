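# Time-resolved band power and nonparametric condition contrasts.

#' Time-frequency decomposition (sliding Hanning windows)
#'
#' 1000 ms Hanning-tapered windows advanced in 50 ms steps give 1 Hz
#' spectral and 20 Hz temporal resolution, up to `fmax` Hz.
#'
#' @param trials 3-D array `[trial, channel, sample]` of epoched data,
#'   or a matrix `[sample, channel]` for a single trial.
#' @param sample_rate Hz.
#' @param t0 time of the first sample relative to stimulus onset, s.
#' @param fmax highest frequency retained, Hz.
#' @param step window step, s.
#' @param window_len window length, s.
#' @return list of class `tfr`: `power[trial, channel, freq, time]`,
#'   `times` (window centers, s), `freqs` (Hz).
#' @export
compute_tfr <- function(trials, sample_rate, t0 = 0, fmax = 200,
                        step = 0.05, window_len = 1) {
  if (is.matrix(trials)) {
    trials <- aperm(array(trials, c(dim(trials), 1)), c(3, 2, 1))
  }
  fs <- sample_rate
  n_win <- round(window_len * fs)
  n_samp <- dim(trials)[3]
  if (n_samp < n_win) stop_invalid("epoch shorter than one analysis window")
  # exact nominal 50 ms grid: per-window start indices are rounded
  # individually so the reported time step is exactly `step`
  k_max <- floor(((n_samp - n_win) / fs) / step)
  starts <- 1 + round((0:k_max) * step * fs)
  w <- hann_window(n_win)
  scale <- 1 / (fs * sum(w^2))
  freq_all <- (0:(floor(n_win / 2))) * fs / n_win
  keep_f <- freq_all <= fmax
  n_tr <- dim(trials)[1]; n_ch <- dim(trials)[2]
  power <- array(0, c(n_tr, n_ch, sum(keep_f), length(starts)))
  widx <- outer(seq_len(n_win) - 1L, starts, `+`)   # n_win x n_steps
  for (tr in seq_len(n_tr)) for (ch in seq_len(n_ch)) {
    x <- trials[tr, ch, ]
    segs <- matrix(x[widx], nrow = n_win) * w
    X <- stats::mvfft(segs)
    p <- Mod(X[which(keep_f), , drop = FALSE])^2 * scale
    dbl <- which(keep_f) > 1 & which(keep_f) < floor(n_win / 2) + 1
    p[dbl, ] <- 2 * p[dbl, ]
    power[tr, ch, , ] <- p
  }
  structure(list(power = power,
                 times = t0 + window_len / 2 + (0:k_max) * step,
                 freqs = freq_all[keep_f]),
            class = "tfr")
}

#' Compensate inter-session offsets in absolute spectral power
#'
#' Regresses the per-session mean power (across all time-frequency
#' estimates in a session) out of every trial, preserving within-session
#' relative structure.  Single-session input is returned unchanged.
#'
#' @param tfr a [compute_tfr()] result.
#' @param sessions session label per trial.
#' @return the corrected `tfr`.
#' @export
correct_session_offsets <- function(tfr, sessions) {
  stopifnot(length(sessions) == dim(tfr$power)[1])
  if (length(unique(sessions)) < 2) return(tfr)
  trial_mean <- apply(tfr$power, 1, mean)
  sess_mean <- tapply(trial_mean, sessions, mean)
  offset <- sess_mean[as.character(sessions)] - mean(trial_mean)
  tfr$power <- tfr$power - array(offset, dim(tfr$power))
  tfr
}

#' Percent change from a bootstrapped pre-stimulus baseline
#'
#' Baseline power per channel x frequency is the average of `n_boot`
#' bootstrap resamples (trials drawn with replacement) of the mean power
#' in the baseline window; the map is then `100 * (power - B) / B`.
#'
#' @param tfr a [compute_tfr()] result.
#' @param window baseline interval `c(from, to)` in s, relative to onset.
#' @param n_boot bootstrap resamples.
#' @param seed optional RNG seed.
#' @return `tfr` with `power` in percent change and the baseline in `$baseline`.
#' @export
baseline_normalize <- function(tfr, window = c(-0.75, -0.50),
                               n_boot = 1000, seed = NULL) {
  bidx <- which(tfr$times >= window[1] & tfr$times <= window[2])
  if (length(bidx) == 0) stop_invalid("baseline window outside epoch")
  n_tr <- dim(tfr$power)[1]
  # per-trial baseline mean, per channel x freq
  bl_tr <- apply(tfr$power[, , , bidx, drop = FALSE], c(1, 2, 3), mean)
  B <- with_seed(seed, {
    acc <- 0
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n_tr, n_tr, replace = TRUE)
      acc <- acc + apply(bl_tr[idx, , , drop = FALSE], c(2, 3), mean)
    }
    acc / n_boot
  })
  if (any(B <= 0)) stop_invalid("non-positive baseline power")
  dm <- dim(tfr$power)
  Bfull <- aperm(array(B, c(dm[2], dm[3], dm[1], dm[4])), c(3, 1, 2, 4))
  tfr$power <- 100 * (tfr$power - Bfull) / Bfull
  tfr$baseline <- B
  tfr
}

#' Band-averaged power time course
#'
#' Averages a TFR over a frequency band, optionally after removing the
#' per-time-point fractal (1/f) contribution predicted from a log-log
#' linear fit over a rhythm-free reference band (default 30-50 Hz).
#' The correction is the package's time-resolved stand-in for IRASA,
#' which itself has no temporal resolution: without it, shared broadband
#' fluctuations inflate correlations between band envelopes.
#'
#' @param tfr a [compute_tfr()] result (absolute power).
#' @param band `c(lo, hi)` Hz.
#' @param fractal_correct regress the shared arrhythmic (1/f) power
#'   fluctuation out of the band time course.  IRASA itself has no
#'   temporal resolution; the package's time-resolved stand-in indexes
#'   the momentary 1/f level by the mean power in a rhythm-free
#'   reference band (default 30-50 Hz) and removes its within-trial
#'   contribution from the band power by per-trial linear regression.
#'   Without this, broadband (1/f) fluctuations shared across the
#'   spectrum inflate correlations between band envelopes.
#' @param fit_band rhythm-free reference band for the correction, Hz.
#' @return array `[trial, channel, time]`.
#' @export
band_power <- function(tfr, band, fractal_correct = FALSE,
                       fit_band = c(30, 50)) {
  fidx <- which(tfr$freqs >= band[1] & tfr$freqs <= band[2])
  if (!length(fidx)) stop_invalid("band outside TFR frequencies")
  bp <- apply(tfr$power[, , fidx, , drop = FALSE], c(1, 2, 4), mean)
  if (!fractal_correct) return(bp)
  ridx <- which(tfr$freqs >= fit_band[1] & tfr$freqs <= fit_band[2] &
                  tfr$freqs > 0)
  if (length(ridx) < 2) stop_invalid("reference band outside TFR frequencies")
  proxy <- apply(tfr$power[, , ridx, , drop = FALSE], c(1, 2, 4), mean)
  nt <- dim(bp)[3]
  pc_ <- proxy - array(rep(apply(proxy, c(1, 2), mean), nt), dim(proxy))
  bc_ <- bp - array(rep(apply(bp, c(1, 2), mean), nt), dim(bp))
  beta <- apply(pc_ * bc_, c(1, 2), sum) /
    pmax(apply(pc_^2, c(1, 2), sum), .Machine$double.xmin)
  bp - array(rep(beta, nt), dim(bp)) * pc_
}

#' Resample a time course to a common duration
#'
#' Maps a series of duration `duration` onto `target` seconds at an
#' unchanged sampling step (anti-alias low-pass before decimation, with
#' linear-extrapolating reflect padding so endpoints are preserved).
#'
#' @param x numeric vector.
#' @param duration current duration, s.
#' @param target target duration, s (default 2).
#' @return resampled vector of length `round(length(x) * target / duration)`.
#' @export
resample_to_common_duration <- function(x, duration, target = 2) {
  n <- length(x)
  n_out <- round(n * target / duration)
  if (n_out == n) return(x)
  if (n_out < n) {
    ratio <- n_out / n          # new Nyquist as a fraction of the old
    x <- fft_zero_phase_filter(x, 1, function(f) {
      # f in cycles/sample (Nyquist 0.5); cosine roll-off to the new Nyquist
      cut <- 0.5 * ratio
      g <- numeric(length(f))
      g[f <= 0.7 * cut] <- 1
      tz <- f > 0.7 * cut & f < cut
      g[tz] <- 0.5 * (1 + cos(pi * (f[tz] - 0.7 * cut) / (0.3 * cut)))
      g
    })
  }
  stats::spline(seq_len(n), x, xout = seq(1, n, length.out = n_out))$y
}

#' Cluster-based permutation test on paired time courses
#'
#' Two-sided dependent-samples t-tests at each time point; contiguous
#' supra-threshold points of common sign form clusters whose mass is the
#' summed t; the null distribution of the maximum cluster mass comes
#' from random sign flips of the paired differences.
#'
#' @param condA,condB matrices `[unit, time]` of paired observations
#'   (units: local-maxima electrodes or participants).
#' @param n_perm randomizations (default 10000).
#' @param alpha cluster significance level.
#' @param cluster_alpha cluster-forming threshold (two-sided t level).
#' @param times optional time axis for reporting.
#' @param seed optional RNG seed.
#' @return list of class `cluster_result`: `clusters` data.frame
#'   (start, end, t_start, t_end, mass, sign, p), `t_series`, `threshold`.
#' @export
cluster_permutation_test <- function(condA, condB, n_perm = 10000,
                                     alpha = 0.05, cluster_alpha = 0.05,
                                     times = NULL, seed = NULL) {
  if (!is.matrix(condA) || !all(dim(condA) == dim(condB)))
    stop_invalid("condA and condB must be matrices of equal dimension")
  n <- nrow(condA)
  if (n < 2) stop_invalid("need >= 2 paired units")
  D <- condA - condB
  nt <- ncol(D)
  tcrit <- stats::qt(1 - cluster_alpha / 2, df = n - 1)
  t_of <- function(m, ssq) {           # mean and raw sum of squares
    v <- (ssq - n * m^2) / (n - 1)
    m / sqrt(pmax(v, .Machine$double.xmin) / n)
  }
  ssq <- colSums(D^2)                  # invariant under sign flips
  t_obs <- t_of(colMeans(D), ssq)

  find_clusters <- function(tv) {
    lab <- sign(tv) * (abs(tv) > tcrit)
    r <- rle(lab)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    keep <- r$values != 0
    if (!any(keep)) return(NULL)
    data.frame(start = starts[keep], end = ends[keep],
               mass = mapply(function(s, e) sum(tv[s:e]),
                             starts[keep], ends[keep]),
               sign = r$values[keep])
  }
  obs <- find_clusters(t_obs)

  max_null <- with_seed(seed, {
    S <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
    M <- S %*% D / n
    vapply(seq_len(n_perm), function(i) {
      tv <- t_of(M[i, ], ssq)
      cl <- find_clusters(tv)
      if (is.null(cl)) 0 else max(abs(cl$mass))
    }, 0)
  })
  if (!is.null(obs)) {
    obs$p <- vapply(obs$mass, function(m)
      (1 + sum(max_null >= abs(m))) / (1 + n_perm), 0)
    if (!is.null(times)) {
      obs$t_start <- times[obs$start]
      obs$t_end <- times[obs$end]
    }
    obs <- obs[order(obs$p), ]
  }
  structure(list(clusters = obs, t_series = t_obs, threshold = tcrit,
                 alpha = alpha, n_perm = n_perm),
            class = "cluster_result")
}

#' Significant clusters at the chosen level
#' @param x a `cluster_result`.
#' @export
significant_clusters <- function(x) {
  if (is.null(x$clusters)) return(NULL)
  x$clusters[x$clusters$p < x$alpha, , drop = FALSE]
}
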