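#' Resample an NN series onto a uniform grid
#'
#' Builds the tachogram by assigning each NN interval value to its onset time
#' (the time of the first beat of the interval) and linearly interpolating
#' onto a uniform grid, including across flagged gaps, so that frequency
#' analysis sees an evenly sampled series.
#'
#' @param nn An [nn_series] with at least 2 intervals.
#' @param fs Resampling frequency, Hz (default 5).
#' @return An [even_series] of NN values (ms) at `fs` Hz.
#' @export
resample_nn <- function(nn, fs = 5) {
  if (length(nn$intervals) < 2L) stop("need at least 2 NN intervals to resample")
  grid <- seq(nn$onset_times[1L], nn$onset_times[length(nn$intervals)],
              by = 1 / fs)
  vals <- approx(nn$onset_times, nn$intervals, xout = grid,
                 method = "linear", rule = 2)$y
  even_series(vals, fs = fs, start_time = grid[1L])
}

#' Resample an irregular beat-domain series onto a uniform grid
#'
#' Linear interpolation of a beat-to-beat measurement (e.g. systolic pressure
#' or R-peak amplitude) onto a uniform grid.
#'
#' @param times Strictly increasing sample times, seconds.
#' @param values Values at `times`.
#' @param fs Target sampling frequency, Hz.
#' @param t_range Optional `c(start, end)` restriction of the grid, seconds.
#' @return An [even_series].
#' @export
resample_series <- function(times, values, fs = 5, t_range = NULL) {
  if (length(times) < 2L) stop("need at least 2 samples to resample")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (is.null(t_range)) t_range <- range(times)
  grid <- seq(t_range[1L], t_range[2L], by = 1 / fs)
  vals <- approx(times, values, xout = grid, method = "linear", rule = 2)$y
  even_series(vals, fs = fs, start_time = grid[1L])
}

# Segment start indices for Welch averaging.
.welch_starts <- function(n, nwin, overlap) {
  step <- max(1L, round(nwin * (1 - overlap)))
  seq.int(1L, n - nwin + 1L, by = step)
}

# Shared Welch engine. Returns one-sided auto-spectra (and the cross-spectrum
# when y is given) with per-segment mean removal and Hann tapering, scaled so
# that the integral of the auto-spectrum over [0, fs/2] matches the series
# variance (Parseval).
.welch_engine <- function(x, y = NULL, fs, window_s, overlap) {
  n <- length(x)
  nwin <- round(window_s * fs)
  if (nwin < 8L) stop("Welch window too short")
  if (n < nwin) stop("series shorter than one Welch window")
  starts <- .welch_starts(n, nwin, overlap)
  w <- signal::hanning(nwin)
  half <- floor(nwin / 2) + 1L
  sxx <- numeric(half)
  syy <- if (!is.null(y)) numeric(half) else NULL
  sxy <- if (!is.null(y)) complex(half) else NULL
  for (s in starts) {
    seg <- x[s:(s + nwin - 1L)]
    X <- fft((seg - mean(seg)) * w)[1:half]
    sxx <- sxx + Mod(X)^2
    if (!is.null(y)) {
      segy <- y[s:(s + nwin - 1L)]
      Y <- fft((segy - mean(segy)) * w)[1:half]
      syy <- syy + Mod(Y)^2
      sxy <- sxy + Conj(X) * Y
    }
  }
  k <- length(starts)
  scale <- 1 / (fs * sum(w^2) * k)
  one_sided <- function(p) {
    p <- p * scale
    # double all bins except DC and (for even nwin) Nyquist
    dbl <- rep(2, half)
    dbl[1L] <- 1
    if (nwin %% 2L == 0L) dbl[half] <- 1
    p * dbl
  }
  out <- list(
    freqs = (0:(half - 1L)) * fs / nwin,
    sxx = one_sided(sxx),
    n_segments = k, nwin = nwin
  )
  if (!is.null(y)) {
    out$syy <- one_sided(syy)
    out$sxy <- one_sided(sxy)
  }
  out
}

# Centered moving average with shrinking window at the edges.
.movavg <- function(x, nb) {
  if (nb < 2L) return(x)
  h <- nb %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - h); hi <- min(n, i + h)
    mean(x[lo:hi])
  }, numeric(1))
}

#' Welch power spectral density
#'
#' Welch periodogram with 50%-overlapped Hann windows of 120-s length (the
#' standard short-term HRV settings), per-segment mean removal only (no
#' linear detrend, so power down to 0.005 Hz is preserved), and an optional
#' frequency-domain moving-average smoothing. The one-sided PSD is scaled so
#' that its integral over `[0, fs/2]` equals the series variance.
#'
#' @param series An [even_series].
#' @param window_s Segment length, seconds (default 120).
#' @param overlap Fractional overlap between segments (default 0.5).
#' @param smooth_bw Moving-average smoothing bandwidth, Hz; `0` disables.
#'   The default 0.01 Hz is narrow enough not to blur the band edges.
#' @return An [hrv_spectrum].
#' @examples
#' t <- seq(0, 960 - 0.2, by = 0.2)
#' x <- even_series(900 + 40 * sin(2 * pi * 0.25 * t), fs = 5)
#' sp <- welch_psd(x)
#' band_powers(sp)$hf  # ~ 40^2 / 2 = 800 ms^2
#' @export
welch_psd <- function(series, window_s = 120, overlap = 0.5,
                      smooth_bw = 0.01) {
  stopifnot(inherits(series, "even_series"))
  eng <- .welch_engine(series$values, fs = series$fs,
                       window_s = window_s, overlap = overlap)
  psd <- eng$sxx
  if (smooth_bw > 0) {
    df <- series$fs / eng$nwin
    psd <- .movavg(psd, round(smooth_bw / df))
  }
  hrv_spectrum(eng$freqs, psd, fs = series$fs, window_s = window_s,
               overlap = overlap, n_segments = eng$n_segments,
               smooth_bw = smooth_bw)
}

# Trapezoidal integral of the PSD over [lo, hi], with the PSD linearly
# interpolated at the band edges so that band widths are exact.
.integrate_band <- function(freqs, psd, lo, hi) {
  if (hi <= lo) return(0)
  lo <- max(lo, freqs[1L]); hi <- min(hi, freqs[length(freqs)])
  inside <- freqs > lo & freqs < hi
  xs <- c(lo, freqs[inside], hi)
  ys <- c(approx(freqs, psd, lo)$y, psd[inside], approx(freqs, psd, hi)$y)
  sum(diff(xs) * (head(ys, -1) + tail(ys, -1)) / 2)
}

#' Band powers of a tachogram spectrum
#'
#' Integrates the periodogram over the standard short-term HRV bands:
#' VLF 0.005-0.04 Hz, LF 0.04-0.15 Hz, HF 0.15-0.40 Hz and total power
#' 0-0.5 Hz, plus the LF/HF ratio. Bands are treated as half-open
#' `[lo, hi)` sub-intervals of the frequency axis; integration is
#' trapezoidal with edge interpolation.
#'
#' @param spec An [hrv_spectrum] covering at least `[0, 0.5]` Hz.
#' @param vlf,lf,hf,total Band edges, Hz.
#' @return A list of class `band_powers` with elements `vlf`, `lf`, `hf`,
#'   `tot_p` (ms^2) and `lf_hf`. `lf_hf` is `NA` (with a warning) when the
#'   HF power is zero.
#' @export
band_powers <- function(spec, vlf = c(0.005, 0.04), lf = c(0.04, 0.15),
                        hf = c(0.15, 0.40), total = c(0, 0.5)) {
  stopifnot(inherits(spec, "hrv_spectrum"))
  if (max(spec$freqs) < total[2L]) {
    stop("spectrum does not cover the requested total-power band")
  }
  f <- spec$freqs; p <- spec$psd
  out <- list(
    vlf = .integrate_band(f, p, vlf[1L], vlf[2L]),
    lf = .integrate_band(f, p, lf[1L], lf[2L]),
    hf = .integrate_band(f, p, hf[1L], hf[2L]),
    tot_p = .integrate_band(f, p, total[1L], total[2L])
  )
  if (out$hf <= 0) {
    warning("HF power is zero: LF/HF ratio undefined")
    out$lf_hf <- NA_real_
  } else {
    out$lf_hf <- out$lf / out$hf
  }
  class(out) <- c("band_powers", "list")
  out
}

#' @export
print.band_powers <- function(x, ...) {
  cat(sprintf(
    "<band_powers> VLF %.1f  LF %.1f  HF %.1f  TOT_P %.1f ms^2  LF/HF %.2f\n",
    x$vlf, x$lf, x$hf, x$tot_p, x$lf_hf
  ))
  invisible(x)
}
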