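#' Detect R peaks with a derivative-and-threshold algorithm
#'
#' Candidate beats are regions where the smoothed squared derivative of the
#' ECG exceeds an adaptive threshold (a fraction of the per-block maximum,
#' floored to a fraction of the global maximum), separated by at least the
#' refractory period. Each peak position is then refined to sub-sample
#' resolution by fitting a parabola to the 3 samples around the local
#' maximum and taking its vertex; amplitudes are the refined peak heights.
#'
#' @param ecg An [ecg_record] of at least 10 s.
#' @param threshold_factor Fraction of the local maximum of the smoothed
#'   squared derivative used as detection threshold.
#' @param refractory_s Minimum separation between accepted peaks, seconds.
#' @param smooth_s Width of the moving-average smoother applied to the
#'   squared derivative, seconds.
#' @param block_s Length of the blocks over which the adaptive threshold is
#'   computed, seconds.
#' @return A [beat_series] (empty, with a warning, for an all-constant
#'   signal).
#' @export
detect_r_peaks <- function(ecg, threshold_factor = 0.3, refractory_s = 0.25,
                           smooth_s = 0.025, block_s = 10) {
  stopifnot(inherits(ecg, "ecg_record"))
  x <- ecg$samples
  fs <- ecg$fs
  if (length(x) < 10 * fs) stop("ECG must be at least 10 s long")
  if (sd(x) == 0) {
    warning("all-constant ECG: no beats detected")
    return(beat_series(numeric(0), numeric(0)))
  }
  d2 <- c(0, diff(x))^2
  nsm <- max(1L, round(smooth_s * fs))
  ssd <- .movavg(d2, nsm)
  # adaptive per-block threshold, floored so silent blocks stay silent
  nb <- max(1L, round(block_s * fs))
  floor_thr <- 0.02 * max(ssd)
  above <- logical(length(ssd))
  for (s in seq.int(1L, length(ssd), by = nb)) {
    e <- min(length(ssd), s + nb - 1L)
    thr <- max(threshold_factor * max(ssd[s:e]), floor_thr)
    above[s:e] <- ssd[s:e] > thr
  }
  if (!any(above)) {
    warning("no threshold crossings: no beats detected")
    return(beat_series(numeric(0), numeric(0)))
  }
  # contiguous runs above threshold -> one candidate peak per run
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- cbind(starts[r$values], ends[r$values])
  pad <- round(0.05 * fs)
  cand <- apply(runs, 1L, function(rg) {
    lo <- max(1L, rg[1L] - pad); hi <- min(length(x), rg[2L] + pad)
    lo + which.max(x[lo:hi]) - 1L
  })
  cand <- sort(unique(cand))
  # refractory dedup: keep the taller of two close peaks
  keep <- integer(0)
  for (k in cand) {
    if (length(keep) && (k - keep[length(keep)]) / fs < refractory_s) {
      if (x[k] > x[keep[length(keep)]]) keep[length(keep)] <- k
    } else {
      keep <- c(keep, k)
    }
  }
  # parabolic vertex refinement on the 3 samples around each maximum
  times <- numeric(length(keep))
  amps <- numeric(length(keep))
  for (j in seq_along(keep)) {
    k <- keep[j]
    if (k > 1L && k < length(x)) {
      y1 <- x[k - 1L]; y2 <- x[k]; y3 <- x[k + 1L]
      den <- y1 - 2 * y2 + y3
      delta <- if (den < 0) 0.5 * (y1 - y3) / den else 0
      delta <- max(-0.5, min(0.5, delta))
      times[j] <- (k - 1L + delta) / fs
      amps[j] <- y2 - 0.25 * (y1 - y3) * delta
    } else {
      times[j] <- (k - 1L) / fs
      amps[j] <- x[k]
    }
  }
  beat_series(times + ecg$start_time, amps)
}

#' Clean a beat series to normal-to-normal intervals
#'
#' Deterministic replacement of interactive artifact editing: an RR interval
#' is flagged non-NN when it is shorter than `premature_frac` or longer than
#' `long_frac` times the running median of the last 11 accepted NN intervals
#' (the global RR median is used until enough intervals are accepted). The
#' beat terminating a too-short interval is labeled premature and both
#' intervals adjacent to a non-normal beat are excluded; too-long intervals
#' are excluded as gaps. Input beats already labeled `premature`/`artifact`,
#' plus any indices in `override_artifact`, are excluded the same way.
#' Contiguity flags mark the resulting gaps.
#'
#' @param beats A [beat_series] with at least 3 beats.
#' @param premature_frac Lower acceptance bound as a fraction of the running
#'   median (default 0.75).
#' @param long_frac Upper acceptance bound as a fraction of the running
#'   median (default 1.5).
#' @param override_artifact Optional integer beat indices to force-relabel
#'   as artifacts (manual review override).
#' @param median_window Number of accepted intervals in the running median.
#' @return An [nn_series]; errors when fewer than 2 NN intervals survive.
#' @examples
#' b <- beat_series(cumsum(c(0, 800, 810, 400, 1200, 805, 795)) / 1000)
#' clean_to_nn(b)  # drops the premature beat and its compensatory pause
#' @export
clean_to_nn <- function(beats, premature_frac = 0.75, long_frac = 1.5,
                        override_artifact = NULL, median_window = 11L) {
  stopifnot(inherits(beats, "beat_series"))
  nb <- length(beats$times)
  if (nb < 3L) stop("need at least 3 beats")
  labels <- as.character(beats$labels)
  if (!is.null(override_artifact)) labels[override_artifact] <- "artifact"
  rr <- diff(beats$times) * 1000
  onset <- beats$times[-nb]
  n <- length(rr)
  global_med <- median(rr)
  excluded <- rep(FALSE, n)
  beat_bad <- labels != "normal"
  accepted <- numeric(0)
  for (i in seq_len(n)) {
    if (beat_bad[i] || beat_bad[i + 1L]) {
      excluded[i] <- TRUE
      next
    }
    med <- if (length(accepted) >= 1L) {
      median(tail(accepted, median_window))
    } else {
      global_med
    }
    if (rr[i] < premature_frac * med) {
      # early beat: mark it premature; both adjacent intervals go
      beat_bad[i + 1L] <- TRUE
      excluded[i] <- TRUE
      if (i < n) excluded[i + 1L] <- TRUE
    } else if (rr[i] > long_frac * med) {
      excluded[i] <- TRUE   # gap (e.g. missed beat), bounding beats kept
    } else {
      accepted <- c(accepted, rr[i])
    }
  }
  keep <- which(!excluded)
  if (length(keep) < 2L) {
    stop("fewer than 2 NN intervals survive cleaning")
  }
  contiguous <- c(FALSE, diff(keep) == 1L)
  nn_series(rr[keep], onset[keep], contiguous)
}

#' Mean NN interval
#'
#' @param nn An [nn_series] with at least one interval.
#' @return Arithmetic mean of the NN intervals, ms.
#' @export
mean_nn <- function(nn) {
  stopifnot(inherits(nn, "nn_series"))
  if (length(nn$intervals) == 0L) stop("empty NN series")
  mean(nn$intervals)
}

#' ECG-derived respiration rate
#'
#' Estimates the breathing rate from the respiratory amplitude modulation of
#' the QRS complexes: the R-peak amplitude series is linearly interpolated
#' onto a uniform grid, high-pass filtered (zero-phase 4th-order
#' Butterworth) to remove oscillations too slow to be respiratory, and the
#' frequency of the highest Welch spectral peak at or above the cutoff is
#' returned. The estimate is invariant to global ECG amplitude scaling.
#'
#' @param beats A [beat_series] with amplitudes, spanning at least 60 s.
#' @param resample_fs Amplitude-series resampling frequency, Hz (default 5).
#' @param highpass_hz High-pass cutoff, Hz (default 0.05).
#' @param window_s Welch segment length, seconds; shortened automatically
#'   for records shorter than the default 120 s.
#' @return Breathing rate, Hz; `NA` with a warning when the amplitude
#'   modulation is absent (no-peak condition).
#' @export
edr <- function(beats, resample_fs = 5, highpass_hz = 0.05, window_s = 120) {
  stopifnot(inherits(beats, "beat_series"))
  if (is.null(beats$amplitudes)) stop("beat series has no amplitudes")
  if (length(beats$times) < 2L || diff(range(beats$times)) < 60) {
    stop("need at least 60 s of beats")
  }
  amp <- resample_series(beats$times, beats$amplitudes, fs = resample_fs)
  if (sd(amp$values) < 1e-12 * max(abs(amp$values), 1e-300)) {
    warning("constant QRS amplitudes: breathing rate undefined")
    return(NA_real_)
  }
  bf <- signal::butter(4, highpass_hz / (resample_fs / 2), type = "high")
  filt <- signal::filtfilt(bf, amp$values - mean(amp$values))
  if (sd(filt) < 1e-10 * sd(amp$values)) {
    warning("no respiratory modulation after high-pass: breathing rate undefined")
    return(NA_real_)
  }
  ws <- min(window_s, floor(length(filt) / resample_fs))
  sp <- welch_psd(even_series(filt, fs = resample_fs), window_s = ws)
  band <- sp$freqs >= highpass_hz
  sp$freqs[band][which.max(sp$psd[band])]
}
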