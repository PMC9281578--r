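# Traditional autonomic function tests: each outcome is an extremum-minus-
# baseline (or ratio) contract on an annotated window. Windows are half-open
# [start, end) in seconds from record start.

# values of a beat-domain series falling in [w[1], w[2])
.in_window <- function(times, values, w) {
  values[times >= w[1L] & times < w[2L]]
}

# beat-domain heart rate (bpm) at interval onsets
.nn_hr <- function(nn) list(times = nn$onset_times, hr = 60000 / nn$intervals)

#' Deep-breathing heart-rate range
#'
#' Difference between the maximum and minimum heart rate (60000/NN, bpm)
#' during the deep-breathing window.
#'
#' @param nn An [nn_series].
#' @param window `c(start_s, end_s)`, at least one breathing cycle long.
#' @return Delta HR, bpm.
#' @export
deep_breathing_dhr <- function(nn, window) {
  hr <- .nn_hr(nn)
  v <- .in_window(hr$times, hr$hr, window)
  if (length(v) == 0L) stop("empty deep-breathing window")
  max(v) - min(v)
}

#' Valsalva ratio
#'
#' Per maneuver, the ratio between the longest RR interval in phase IV and
#' the shortest RR interval in phase II; the test outcome is the largest
#' ratio across maneuvers. Maneuvers with an empty phase window are skipped
#' with a warning.
#'
#' @param nn An [nn_series].
#' @param maneuvers List of maneuvers; each a list with elements `phase2`
#'   and `phase4`, both `c(start_s, end_s)` windows.
#' @return The Valsalva ratio (>= 1 for physiological responses).
#' @export
valsalva_ratio <- function(nn, maneuvers) {
  if (length(maneuvers) == 0L) stop("no Valsalva maneuvers supplied")
  ratios <- vapply(maneuvers, function(mv) {
    rr2 <- .in_window(nn$onset_times, nn$intervals, mv$phase2)
    rr4 <- .in_window(nn$onset_times, nn$intervals, mv$phase4)
    if (length(rr2) == 0L || length(rr4) == 0L) {
      warning("maneuver with empty phase window skipped")
      return(NA_real_)
    }
    max(rr4) / min(rr2)
  }, numeric(1))
  if (all(is.na(ratios))) stop("all maneuvers had empty phase windows")
  max(ratios, na.rm = TRUE)
}

#' Handgrip diastolic pressure rise
#'
#' Maximal diastolic pressure during sustained contraction minus the mean
#' baseline diastolic pressure. Negative values are returned unclamped.
#'
#' @param dbp Data frame with columns `time` (s) and `value` (mmHg).
#' @param baseline_window,grip_window `c(start_s, end_s)` windows.
#' @return Delta DBP, mmHg.
#' @export
handgrip_ddbp <- function(dbp, baseline_window, grip_window) {
  base <- .in_window(dbp$time, dbp$value, baseline_window)
  grip <- .in_window(dbp$time, dbp$value, grip_window)
  if (length(base) == 0L || length(grip) == 0L) stop("empty handgrip window")
  max(grip) - mean(base)
}

#' Head-up tilt 30:15 ratio
#'
#' Ratio between the longest RR interval around the 30th beat after tilt
#' and the shortest RR interval around the 15th beat. "Around" defaults to
#' beats 25-35 and 10-20 post-tilt.
#'
#' @param nn An [nn_series] with at least 40 beats after `tilt_start`.
#' @param tilt_start Tilt onset, seconds.
#' @param around_15,around_30 Beat-index windows (inclusive) after tilt.
#' @return The 30:15 ratio.
#' @export
hut_3015 <- function(nn, tilt_start, around_15 = c(10, 20),
                     around_30 = c(25, 35)) {
  post <- nn$intervals[nn$onset_times >= tilt_start]
  if (length(post) < 40L) stop("need at least 40 beats after tilt onset")
  r15 <- post[around_15[1L]:around_15[2L]]
  r30 <- post[around_30[1L]:around_30[2L]]
  max(r30) / min(r15)
}

#' Head-up tilt systolic pressure fall
#'
#' Lowest systolic pressure during the first minutes of tilt minus the mean
#' baseline value (typically negative).
#'
#' @param sbp Data frame with columns `time` (s) and `value` (mmHg).
#' @param baseline_window `c(start_s, end_s)` pre-tilt window.
#' @param tilt_start Tilt onset, seconds.
#' @param horizon_s Length of the post-tilt search window (default 180 s).
#' @return Delta SBP, mmHg (negative for a pressure fall).
#' @export
hut_dsbp <- function(sbp, baseline_window, tilt_start, horizon_s = 180) {
  base <- .in_window(sbp$time, sbp$value, baseline_window)
  tilt <- .in_window(sbp$time, sbp$value,
                     c(tilt_start, tilt_start + horizon_s))
  if (length(base) == 0L || length(tilt) == 0L) stop("empty HUT window")
  min(tilt) - mean(base)
}

#' Cold pressor diastolic pressure response
#'
#' Maximal diastolic pressure during immersion minus the mean baseline
#' value. The immersion window is clamped to `max_immersion_s` (90 s, the
#' standard immersion duration); samples outside it are ignored.
#'
#' @param dbp Data frame with columns `time` (s) and `value` (mmHg).
#' @param baseline_window,immersion_window `c(start_s, end_s)` windows.
#' @param max_immersion_s Maximum immersion length, seconds.
#' @return Delta DBP, mmHg.
#' @export
cold_pressor_ddbp <- function(dbp, baseline_window, immersion_window,
                              max_immersion_s = 90) {
  immersion_window <- .clamp_immersion(immersion_window, max_immersion_s)
  base <- .in_window(dbp$time, dbp$value, baseline_window)
  imm <- .in_window(dbp$time, dbp$value, immersion_window)
  if (length(base) == 0L || length(imm) == 0L) stop("empty cold-pressor window")
  max(imm) - mean(base)
}

#' Cold pressor heart-rate response
#'
#' Highest heart rate during immersion minus the mean baseline heart rate.
#'
#' @param nn An [nn_series].
#' @inheritParams cold_pressor_ddbp
#' @return Delta HR, bpm.
#' @export
cold_pressor_dhr <- function(nn, baseline_window, immersion_window,
                             max_immersion_s = 90) {
  immersion_window <- .clamp_immersion(immersion_window, max_immersion_s)
  hr <- .nn_hr(nn)
  base <- .in_window(hr$times, hr$hr, baseline_window)
  imm <- .in_window(hr$times, hr$hr, immersion_window)
  if (length(base) == 0L || length(imm) == 0L) stop("empty cold-pressor window")
  max(imm) - mean(base)
}

.clamp_immersion <- function(w, max_s) {
  if (diff(w) > max_s) {
    warning("immersion window clamped to ", max_s, " s")
    w[2L] <- w[1L] + max_s
  }
  w
}

#' Default Ewing battery score thresholds
#'
#' Editable cut-off table for the five Ewing tests. Every test is expressed
#' so that higher values are better: an outcome `>= normal_min` scores 0
#' (normal), `>= borderline_min` scores 0.5 (borderline), below that 1
#' (abnormal). The tilt systolic fall is encoded as the signed Delta SBP
#' (a fall of 30 mmHg is -30). The defaults follow the classical autonomic
#' test battery literature; they are configuration, not constants of this
#' package.
#'
#' @return A data frame with columns `test`, `normal_min`, `borderline_min`.
#' @export
ewing_thresholds <- function() {
  data.frame(
    test = c("deep_breathing", "valsalva", "handgrip", "hut_3015",
             "hut_dsbp"),
    normal_min = c(15, 1.21, 16, 1.04, -10),
    borderline_min = c(11, 1.11, 11, 1.01, -29),
    stringsAsFactors = FALSE
  )
}

#' Ewing's autonomic score
#'
#' Scores each of the five Ewing test outcomes 0 (normal), 0.5 (borderline)
#' or 1 (abnormal) against the threshold table and sums them; the total
#' ranges 0-5 in steps of 0.5.
#'
#' @param outcomes Named list or vector with elements `deep_breathing`
#'   (bpm), `valsalva` (ratio), `handgrip` (mmHg), `hut_3015` (ratio) and
#'   `hut_dsbp` (signed mmHg).
#' @param thresholds Threshold table as from [ewing_thresholds()].
#' @return Total Ewing score.
#' @export
ewing_score <- function(outcomes, thresholds = ewing_thresholds()) {
  missing <- setdiff(thresholds$test, names(outcomes))
  if (length(missing)) {
    stop("missing Ewing outcome(s): ", paste(missing, collapse = ", "))
  }
  scores <- vapply(seq_len(nrow(thresholds)), function(i) {
    v <- as.numeric(outcomes[[thresholds$test[i]]])
    if (is.na(v)) stop("NA Ewing outcome: ", thresholds$test[i])
    if (v >= thresholds$normal_min[i]) 0
    else if (v >= thresholds$borderline_min[i]) 0.5
    else 1
  }, numeric(1))
  sum(scores)
}

#' SCOPA-AUT autonomic symptom score
#'
#' Sum of the 23 item responses expressed as a percentage of the maximum
#' achievable score. Missing items are prorated by default (dropped from
#' both numerator and denominator).
#'
#' @param items Numeric vector of item responses (NA = missing).
#' @param item_max Per-item maxima (default: 3 points per item).
#' @param missing `"prorate"` or `"error"`.
#' @return Score in percent, 0-100.
#' @export
scopa_score <- function(items, item_max = rep(3, length(items)),
                        missing = c("prorate", "error")) {
  missing <- match.arg(missing)
  if (length(items) != length(item_max)) stop("items/item_max length mismatch")
  if (anyNA(items)) {
    if (missing == "error") stop("missing SCOPA-AUT item response")
    keep <- !is.na(items)
    items <- items[keep]; item_max <- item_max[keep]
    if (length(items) == 0L) stop("all items missing")
  }
  if (any(items < 0 | items > item_max)) {
    stop("item response out of range")
  }
  100 * sum(items) / sum(item_max)
}
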