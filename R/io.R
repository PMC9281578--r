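# Plain-text I/O for the standard exchange formats of the pipeline:
# two-column ECG CSV, beat CSV, cohort CSV, spectrum/profile CSV and JSON
# test annotations.

#' Read an ECG from a two-column CSV
#'
#' Expects columns `t` (seconds) and `value` (voltage); the sampling
#' frequency is inferred from the median time step unless given.
#'
#' @param path CSV file path.
#' @param fs Optional sampling frequency override, Hz.
#' @return An [ecg_record].
#' @export
read_ecg_csv <- function(path, fs = NULL) {
  d <- read.csv(path)
  if (ncol(d) < 2L) stop("ECG CSV needs two columns (t, value)")
  t <- d[[1L]]; v <- d[[2L]]
  if (is.null(fs)) fs <- 1 / median(diff(t))
  ecg_record(v, fs = fs, start_time = t[1L])
}

#' Write / read a beat series as CSV
#'
#' Columns: `t_s`, `amplitude`, `label`.
#'
#' @param beats A [beat_series].
#' @param path CSV file path.
#' @return `write_beats_csv` returns `path` invisibly; `read_beats_csv`
#'   returns a [beat_series].
#' @export
write_beats_csv <- function(beats, path) {
  stopifnot(inherits(beats, "beat_series"))
  amp <- if (is.null(beats$amplitudes)) NA_real_ else beats$amplitudes
  write.csv(data.frame(t_s = beats$times, amplitude = amp,
                       label = as.character(beats$labels)),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_beats_csv
#' @export
read_beats_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("t_s", "amplitude", "label")
  if (!all(need %in% names(d))) {
    stop("beat CSV needs columns ", paste(need, collapse = ", "))
  }
  amp <- if (all(is.na(d$amplitude))) NULL else d$amplitude
  beat_series(d$t_s, amp, d$label)
}

#' Write / read a cohort table as CSV
#'
#' Long format: `subject_id`, `group`, `condition`, `index`, `value`.
#'
#' @param cohort A `cohort_table` data frame.
#' @param path CSV file path.
#' @return `write_cohort_csv` returns `path` invisibly; `read_cohort_csv`
#'   returns a `cohort_table`.
#' @export
write_cohort_csv <- function(cohort, path) {
  need <- c("subject_id", "group", "condition", "index", "value")
  if (!all(need %in% names(cohort))) {
    stop("cohort must have columns ", paste(need, collapse = ", "))
  }
  write.csv(cohort[, need], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "condition", "index", "value")
  if (!all(need %in% names(d))) {
    stop("cohort CSV needs columns ", paste(need, collapse = ", "))
  }
  class(d) <- c("cohort_table", "data.frame")
  d
}

#' Export a spectrum or multiscale profile as CSV
#'
#' @param x An [hrv_spectrum] or [multiscale_profile].
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_spectrum_csv <- function(x, path) {
  stopifnot(inherits(x, "hrv_spectrum"))
  write.csv(data.frame(freq_hz = x$freqs, psd = x$psd), path,
            row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectrum_csv
#' @export
write_profile_csv <- function(x, path) {
  stopifnot(inherits(x, "multiscale_profile"))
  write.csv(data.frame(tau_s = x$tau_s, beat_scale = x$beat_scales,
                       value = x$values), path, row.names = FALSE)
  invisible(path)
}

#' Read autonomic-test annotations from JSON
#'
#' Expects an array of objects with fields `test`, `window`, `start_s`,
#' `end_s` (e.g. `{"test": "valsalva", "window": "phase2", "start_s": 10,
#' "end_s": 25}`), validated and returned as a data frame.
#'
#' @param path JSON file path.
#' @return A data frame with one row per annotated window.
#' @export
read_annotations <- function(path) {
  a <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  need <- c("test", "window", "start_s", "end_s")
  if (!all(need %in% names(a))) {
    stop("annotations need fields ", paste(need, collapse = ", "))
  }
  if (any(a$end_s <= a$start_s)) stop("annotation windows must have end_s > start_s")
  a[, need]
}
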