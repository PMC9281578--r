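#' pNN50 (directional)
#'
#' Percentage of successive NN pairs whose difference is at least +50 ms
#' (`"plus"`) or at most -50 ms (`"minus"`). Only contiguous pairs count:
#' pairs spanning a flagged gap are excluded from both the numerator and the
#' denominator, and the comparison is inclusive (>= 50 ms).
#'
#' @param nn An [nn_series] with at least 2 contiguous intervals.
#' @param direction `"plus"` or `"minus"`.
#' @param threshold_ms Difference threshold, ms (default 50).
#' @return Percentage in `[0, 100]`.
#' @examples
#' pnn50(nn_series(c(800, 860, 820, 880)), "plus")  # 66.7
#' @export
pnn50 <- function(nn, direction = c("plus", "minus"), threshold_ms = 50) {
  direction <- match.arg(direction)
  d <- .nn_diffs(nn)
  if (length(d) == 0L) stop("no contiguous successive NN pairs")
  hits <- if (direction == "plus") d >= threshold_ms else d <= -threshold_ms
  100 * sum(hits) / length(d)
}

#' RMSSD
#'
#' Root-mean-square of successive NN differences over contiguous pairs, a
#' marker of cardiac vagal activity.
#'
#' @param nn An [nn_series] with at least 2 contiguous intervals.
#' @return RMSSD, ms.
#' @export
rmssd <- function(nn) {
  d <- .nn_diffs(nn)
  if (length(d) == 0L) stop("no contiguous successive NN pairs")
  sqrt(mean(d^2))
}

#' SDNN index
#'
#' Mean of the standard deviations (sample, n-1 denominator) of NN intervals
#' computed over a running window, the conventional short-term index of
#' global variability.
#'
#' @param nn An [nn_series] spanning at least `window_s` seconds.
#' @param window_s Window length, seconds (default 300, i.e. 5 min).
#' @param step_s Window step, seconds (default 60).
#' @param min_beats Windows with fewer intervals are skipped with a warning.
#' @return SDNN index, ms.
#' @export
sdnn_index <- function(nn, window_s = 300, step_s = 60, min_beats = 30) {
  total <- nn_duration(nn)
  if (total < window_s) {
    stop("record shorter than one window; consider the plain SD of NN instead")
  }
  t0 <- nn$onset_times[1L]
  starts <- seq(t0, t0 + total - window_s, by = step_s)
  sds <- vapply(starts, function(s) {
    idx <- nn$onset_times >= s & nn$onset_times < s + window_s
    if (sum(idx) < min_beats) NA_real_ else sd(nn$intervals[idx])
  }, numeric(1))
  if (anyNA(sds)) {
    warning(sum(is.na(sds)), " window(s) with fewer than ", min_beats,
            " intervals skipped")
    sds <- sds[!is.na(sds)]
  }
  if (length(sds) == 0L) stop("no window with enough intervals")
  mean(sds)
}

#' All time-domain HRV indexes
#'
#' @param nn An [nn_series].
#' @param ... Passed to [sdnn_index()].
#' @return A one-row data frame with `nni_m`, `pnn50_plus`, `pnn50_minus`,
#'   `rmssd` (ms or %) and `sdnn_i` (`NA` when the record is shorter than
#'   one SDNN window).
#' @export
time_domain_indexes <- function(nn, ...) {
  sdnn_i <- tryCatch(sdnn_index(nn, ...), error = function(e) NA_real_)
  data.frame(
    nni_m = mean_nn(nn),
    pnn50_plus = pnn50(nn, "plus"),
    pnn50_minus = pnn50(nn, "minus"),
    rmssd = rmssd(nn),
    sdnn_i = sdnn_i
  )
}
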