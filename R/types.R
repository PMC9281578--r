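#' Normal-to-normal (NN) interval series
#'
#' The central container of the package: a sequence of artifact-free cardiac
#' interbeat intervals in milliseconds together with the onset time of each
#' interval (the time of its first beat, seconds from record start) and a
#' contiguity flag stating whether an interval immediately follows the
#' previous one (no rejected beats in between). Every HRV index operates on
#' this object.
#'
#' @param intervals Numeric vector of NN intervals, ms. Must be positive and
#'   finite.
#' @param onset_times Optional numeric vector of onset times in seconds
#'   (strictly increasing, same length as `intervals`). When omitted the
#'   series is assumed gap-free and onsets are accumulated from the intervals.
#' @param contiguous Optional logical vector: `contiguous[i]` is `TRUE` when
#'   interval `i` starts at the beat that ends interval `i - 1`. The first
#'   element is always `FALSE` (no predecessor). Defaults to a fully
#'   contiguous series.
#' @return An object of class `nn_series`.
#' @examples
#' nn <- nn_series(c(800, 810, 795, 805))
#' mean_nn(nn)
#' @export
nn_series <- function(intervals, onset_times = NULL, contiguous = NULL) {
  intervals <- as.numeric(intervals)
  n <- length(intervals)
  if (n == 0L) stop("empty NN series")
  if (any(!is.finite(intervals)) || any(intervals <= 0)) {
    stop("NN intervals must be positive and finite (ms)")
  }
  if (is.null(onset_times)) {
    onset_times <- cumsum(c(0, intervals[-n])) / 1000
  } else {
    onset_times <- as.numeric(onset_times)
    if (length(onset_times) != n) stop("onset_times length mismatch")
    if (any(diff(onset_times) <= 0)) stop("onset_times must be strictly increasing")
  }
  if (is.null(contiguous)) {
    contiguous <- c(FALSE, rep(TRUE, n - 1L))
  } else {
    contiguous <- as.logical(contiguous)
    if (length(contiguous) != n) stop("contiguous length mismatch")
    contiguous[1L] <- FALSE
  }
  structure(
    list(intervals = intervals, onset_times = onset_times,
         contiguous = contiguous),
    class = "nn_series"
  )
}

#' @export
print.nn_series <- function(x, ...) {
  n <- length(x$intervals)
  cat(sprintf(
    "<nn_series> %d intervals, %.1f s, mean NN %.1f ms, %d gap(s)\n",
    n, nn_duration(x), mean(x$intervals), sum(!x$contiguous[-1L])
  ))
  invisible(x)
}

#' @export
length.nn_series <- function(x) length(x$intervals)

#' Total duration spanned by an NN series
#'
#' @param nn An [nn_series].
#' @return Seconds from the onset of the first interval to the end of the
#'   last one.
#' @export
nn_duration <- function(nn) {
  n <- length(nn$intervals)
  nn$onset_times[n] + nn$intervals[n] / 1000 - nn$onset_times[1L]
}

# Indexes i such that (i - 1, i) is a valid successive NN pair.
.nn_pair_idx <- function(nn) {
  which(nn$contiguous & seq_along(nn$intervals) > 1L)
}

# Successive differences NN[i] - NN[i-1] over contiguous pairs only.
.nn_diffs <- function(nn) {
  i <- .nn_pair_idx(nn)
  nn$intervals[i] - nn$intervals[i - 1L]
}

#' Detected beat series
#'
#' R-peak occurrence times, refined peak amplitudes and per-beat labels, the
#' bridge between the raw ECG and all interval-based analysis.
#'
#' @param times Strictly increasing beat times, seconds.
#' @param amplitudes Optional refined R-peak amplitudes (same units as the
#'   ECG), used by ECG-derived respiration.
#' @param labels Optional per-beat labels; one of `"normal"`, `"premature"`,
#'   `"artifact"`. Defaults to all-normal.
#' @return An object of class `beat_series`.
#' @export
beat_series <- function(times, amplitudes = NULL, labels = NULL) {
  times <- as.numeric(times)
  n <- length(times)
  if (n > 1L && any(diff(times) <= 0)) stop("beat times must be strictly increasing")
  if (!is.null(amplitudes)) {
    amplitudes <- as.numeric(amplitudes)
    if (length(amplitudes) != n) stop("amplitudes length mismatch")
  }
  lv <- c("normal", "premature", "artifact")
  if (is.null(labels)) labels <- rep("normal", n)
  labels <- as.character(labels)
  if (length(labels) != n) stop("labels length mismatch")
  if (!all(labels %in% lv)) stop("labels must be one of: ", paste(lv, collapse = ", "))
  structure(
    list(times = times, amplitudes = amplitudes,
         labels = factor(labels, levels = lv)),
    class = "beat_series"
  )
}

#' @export
print.beat_series <- function(x, ...) {
  cat(sprintf(
    "<beat_series> %d beats over %.1f s (%d non-normal)\n",
    length(x$times),
    if (length(x$times)) diff(range(x$times)) else 0,
    sum(x$labels != "normal")
  ))
  invisible(x)
}

#' @export
length.beat_series <- function(x) length(x$times)

#' Uniformly sampled series
#'
#' A signal on a uniform time grid, e.g. the 5-Hz resampled tachogram or a
#' resampled systolic pressure series.
#'
#' @param values Numeric samples (ms for tachograms, mmHg for pressures).
#' @param fs Sampling frequency, Hz.
#' @param start_time Time of the first sample, seconds.
#' @return An object of class `even_series`.
#' @export
even_series <- function(values, fs, start_time = 0) {
  values <- as.numeric(values)
  if (!is.numeric(fs) || fs <= 0) stop("fs must be positive")
  if (any(!is.finite(values))) stop("values must be finite")
  structure(list(values = values, fs = fs, start_time = start_time),
            class = "even_series")
}

#' @export
print.even_series <- function(x, ...) {
  cat(sprintf("<even_series> %d samples at %g Hz (%.1f s)\n",
              length(x$values), x$fs, length(x$values) / x$fs))
  invisible(x)
}

#' Raw ECG record
#'
#' @param samples Voltage samples.
#' @param fs Sampling frequency, Hz (1000 Hz in the typical acquisition).
#' @param start_time Time of the first sample, seconds.
#' @param label Channel label.
#' @return An object of class `ecg_record`.
#' @export
ecg_record <- function(samples, fs, start_time = 0, label = "ECG") {
  samples <- as.numeric(samples)
  if (!is.numeric(fs) || fs <= 0) stop("fs must be positive")
  if (any(!is.finite(samples))) stop("ECG samples must be finite")
  structure(list(samples = samples, fs = fs, start_time = start_time,
                 label = label),
            class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record> '%s': %d samples at %g Hz (%.1f s)\n",
              x$label, length(x$samples), x$fs, length(x$samples) / x$fs))
  invisible(x)
}

#' Power spectral density estimate
#'
#' One-sided Welch power spectral density with its estimation metadata.
#'
#' @param freqs Frequency grid, Hz (ascending, from 0).
#' @param psd Power spectral density, e.g. ms^2/Hz.
#' @param fs Sampling frequency of the analysed series.
#' @param window_s Segment length, seconds.
#' @param overlap Fractional segment overlap.
#' @param n_segments Number of averaged segments.
#' @param smooth_bw Frequency-domain smoothing bandwidth, Hz (0 = none).
#' @return An object of class `hrv_spectrum`.
#' @export
hrv_spectrum <- function(freqs, psd, fs, window_s, overlap, n_segments,
                         smooth_bw = 0) {
  if (length(freqs) != length(psd)) stop("freqs/psd length mismatch")
  if (any(diff(freqs) <= 0) || freqs[1L] < 0) stop("freqs must be ascending and nonnegative")
  psd <- pmax(psd, 0)
  structure(
    list(freqs = freqs, psd = psd, fs = fs, window_s = window_s,
         overlap = overlap, n_segments = n_segments, smooth_bw = smooth_bw),
    class = "hrv_spectrum"
  )
}

#' @export
print.hrv_spectrum <- function(x, ...) {
  cat(sprintf(
    "<hrv_spectrum> %d bins to %.3g Hz (%g-s windows, %d segments)\n",
    length(x$freqs), max(x$freqs), x$window_s, x$n_segments
  ))
  invisible(x)
}

#' @export
plot.hrv_spectrum <- function(x, log = "y", xlim = c(0, 0.5),
                              xlab = "Frequency (Hz)",
                              ylab = "PSD (ms²/Hz)", type = "l", ...) {
  keep <- x$freqs >= xlim[1] & x$freqs <= xlim[2]
  y <- x$psd[keep]
  if (identical(log, "y")) y <- pmax(y, .Machine$double.xmin)
  plot(x$freqs[keep], y, type = type, log = log, xlab = xlab, ylab = ylab, ...)
  abline(v = c(0.005, 0.04, 0.15, 0.40), col = "grey", lty = 3)
  invisible(x)
}

#' Multiscale profile (MSE or DFA coefficient vs scale)
#'
#' A per-scale profile: multiscale entropy MSE(tau) or the scale-dependent
#' self-similarity coefficient alpha(tau), with scales expressed both in
#' beats and in seconds (beat scale times the mean NN interval).
#'
#' @param tau_s Scale in seconds (ascending).
#' @param values Profile values (nats for MSE, dimensionless for alpha).
#' @param beat_scales Integer beat scales mapped to `tau_s`.
#' @param kind `"mse"` or `"alpha"`.
#' @return An object of class `multiscale_profile`.
#' @export
multiscale_profile <- function(tau_s, values, beat_scales,
                               kind = c("mse", "alpha")) {
  kind <- match.arg(kind)
  if (length(tau_s) != length(values) || length(tau_s) != length(beat_scales)) {
    stop("tau_s, values and beat_scales must have equal length")
  }
  if (any(diff(tau_s) <= 0)) stop("tau_s must be ascending")
  structure(
    list(tau_s = tau_s, values = values, beat_scales = beat_scales,
         kind = kind),
    class = "multiscale_profile"
  )
}

#' @export
print.multiscale_profile <- function(x, ...) {
  cat(sprintf("<multiscale_profile> %s over %d scales, tau %.2f-%.2f s\n",
              toupper(x$kind), length(x$tau_s), min(x$tau_s), max(x$tau_s)))
  invisible(x)
}

#' @export
plot.multiscale_profile <- function(x, xlab = "tau (s)",
                                    ylab = NULL, type = "b", ...) {
  if (is.null(ylab)) {
    ylab <- if (x$kind == "mse") "MSE(tau) (nats)" else "alpha(tau)"
  }
  plot(x$tau_s, x$values, type = type, xlab = xlab, ylab = ylab, ...)
  invisible(x)
}
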