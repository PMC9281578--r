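#' Transfer-function baroreflex sensitivity
#'
#' Estimates baroreflex sensitivity (BRS) from aligned, uniformly resampled
#' systolic blood pressure and NN-interval series: the SBP->NNI transfer
#' gain is `|S_xy(f)| / S_xx(f)` (ms/mmHg, with the SBP auto-spectrum in
#' the denominator — the only reading dimensionally consistent with
#' ms/mmHg), the squared coherency is `|S_xy|^2 / (S_xx S_yy)`, both from
#' Welch cross-/auto-spectra with the standard 120-s Hann, 50%-overlap
#' segmentation, and BRS and the LF coherency are their unweighted means
#' over the LF band (0.04-0.15 Hz). At least 3 Welch segments are required
#' (coherency of a single segment is identically 1).
#'
#' @param sbp An [even_series] of systolic pressure, mmHg.
#' @param nni An [even_series] of NN intervals, ms, same `fs`, time-aligned.
#' @param lf_band LF band edges, Hz.
#' @param window_s,overlap Welch settings (see [welch_psd()]).
#' @return A list of class `baroreflex_result`: `brs` (ms/mmHg),
#'   `lf_coherency`, and per-frequency `freqs`, `gain`, `coherency` curves.
#'   `brs`/`lf_coherency` are `NA` with a warning when SBP has no LF power.
#' @examples
#' sim <- generate_coupled_sbp_rr(baro_coupling_config(gain = 10, seed = 1))
#' brs_from_beats(sim$sbp, sim$nn)$brs  # ~10 ms/mmHg
#' @export
brs_transfer <- function(sbp, nni, lf_band = c(0.04, 0.15),
                         window_s = 120, overlap = 0.5) {
  stopifnot(inherits(sbp, "even_series"), inherits(nni, "even_series"))
  if (sbp$fs != nni$fs) stop("series must share the sampling frequency")
  n <- min(length(sbp$values), length(nni$values))
  if (n / sbp$fs < 240) stop("need at least 240 s of aligned series")
  eng <- .welch_engine(sbp$values[1:n], nni$values[1:n], fs = sbp$fs,
                       window_s = window_s, overlap = overlap)
  if (eng$n_segments < 3L) {
    stop("need at least 3 Welch segments for a meaningful coherency")
  }
  gain <- ifelse(eng$sxx > 0, Mod(eng$sxy) / eng$sxx, NA_real_)
  coh <- ifelse(eng$sxx > 0 & eng$syy > 0,
                pmin(1, Mod(eng$sxy)^2 / (eng$sxx * eng$syy)), NA_real_)
  lf <- eng$freqs >= lf_band[1L] & eng$freqs < lf_band[2L]
  lf_sxx <- sum(eng$sxx[lf])
  if (!any(lf) || lf_sxx <= 0 || all(is.na(gain[lf]))) {
    warning("no SBP variance in the LF band: BRS undefined")
    brs <- NA_real_; lf_coh <- NA_real_
  } else {
    brs <- mean(gain[lf], na.rm = TRUE)
    lf_coh <- mean(coh[lf], na.rm = TRUE)
  }
  structure(
    list(brs = brs, lf_coherency = lf_coh, freqs = eng$freqs, gain = gain,
         coherency = coh, n_segments = eng$n_segments),
    class = "baroreflex_result"
  )
}

#' @export
print.baroreflex_result <- function(x, ...) {
  cat(sprintf(
    "<baroreflex_result> BRS %.2f ms/mmHg, LF coherency %.2f (%d segments)\n",
    x$brs, x$lf_coherency, x$n_segments
  ))
  invisible(x)
}

#' Baroreflex sensitivity from beat-domain series
#'
#' Resamples a beat-to-beat systolic pressure series and an NN series at
#' 5 Hz on their common time span and applies [brs_transfer()].
#'
#' @param sbp Data frame with columns `time` (s) and `value` (mmHg).
#' @param nn An [nn_series].
#' @param fs Resampling frequency, Hz (default 5).
#' @param ... Passed to [brs_transfer()].
#' @return A `baroreflex_result`.
#' @export
brs_from_beats <- function(sbp, nn, fs = 5, ...) {
  stopifnot(inherits(nn, "nn_series"),
            all(c("time", "value") %in% names(sbp)))
  t0 <- max(min(sbp$time), nn$onset_times[1L])
  t1 <- min(max(sbp$time), nn$onset_times[length(nn$intervals)])
  if (t1 - t0 < 240) stop("need at least 240 s of overlapping series")
  sbp_even <- resample_series(sbp$time, sbp$value, fs = fs,
                              t_range = c(t0, t1))
  nni_even <- resample_series(nn$onset_times, nn$intervals, fs = fs,
                              t_range = c(t0, t1))
  brs_transfer(sbp_even, nni_even, ...)
}
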