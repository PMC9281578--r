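# End-to-end orchestration: NN series (+ optional SBP) per condition ->
# full index record per subject -> cohort table -> ROC report.

# All 15 HRV indexes for one NN series, with explicit availability.
# Preconditions: spectra need >= 2 Welch windows (240 s), SDNN_i one 300-s
# window, MSE >= 250 intervals, DFA >= 500 intervals.
.index_names <- c("NNI_m", "pNN50+", "pNN50-", "RMSSD", "SDNN_i",
                  "TOT_P", "VLF", "LF", "HF", "LF_HF",
                  "alpha_short", "alpha_long", "SampEn", "MSE_HF", "MSE_LF")

#' Compute every HRV index for one NN series
#'
#' Computes the full index set (time domain, Welch band powers of the 5-Hz
#' tachogram, sample entropy, multiscale entropy band averages, multiscale
#' DFA band averages). Indexes whose preconditions the record cannot meet
#' are reported as unavailable with an explicit reason instead of failing.
#'
#' @param nn An [nn_series].
#' @param sampen_m,sampen_r_frac Sample entropy settings (defaults m = 1,
#'   r = 15% of the series SD).
#' @param welch_window_s Welch segment length, seconds.
#' @return A data frame with columns `index`, `value`, `available`,
#'   `reason`.
#' @export
hrv_indexes <- function(nn, sampen_m = 1, sampen_r_frac = 0.15,
                        welch_window_s = 120) {
  stopifnot(inherits(nn, "nn_series"))
  dur <- nn_duration(nn)
  nbeats <- length(nn$intervals)
  val <- setNames(rep(NA_real_, length(.index_names)), .index_names)
  reason <- setNames(rep(NA_character_, length(.index_names)), .index_names)

  val[["NNI_m"]] <- mean_nn(nn)
  val[["pNN50+"]] <- pnn50(nn, "plus")
  val[["pNN50-"]] <- pnn50(nn, "minus")
  val[["RMSSD"]] <- rmssd(nn)

  if (dur >= 300) {
    val[["SDNN_i"]] <- sdnn_index(nn)
  } else {
    reason[["SDNN_i"]] <- "record shorter than one 300-s window"
  }

  spectral_ix <- c("TOT_P", "VLF", "LF", "HF", "LF_HF")
  if (dur >= 2 * welch_window_s) {
    bp <- band_powers(welch_psd(resample_nn(nn), window_s = welch_window_s))
    val[spectral_ix] <- c(bp$tot_p, bp$vlf, bp$lf, bp$hf, bp$lf_hf)
  } else {
    reason[spectral_ix] <- "record shorter than two Welch windows"
  }

  if (nbeats >= 250) {
    val[["SampEn"]] <- sampen(nn$intervals, m = sampen_m,
                              r = sampen_r_frac * sd(nn$intervals))
    mb <- mse_bands(mse_profile(nn, m = sampen_m, r_frac = sampen_r_frac))
    val[["MSE_HF"]] <- mb$mse_hf
    val[["MSE_LF"]] <- mb$mse_lf
  } else {
    reason[c("SampEn", "MSE_HF", "MSE_LF")] <- "fewer than 250 NN intervals"
  }

  if (nbeats >= 500) {
    ab <- alpha_bands(mdfa_profile(nn))
    val[["alpha_short"]] <- ab$alpha_short
    val[["alpha_long"]] <- ab$alpha_long
  } else {
    reason[c("alpha_short", "alpha_long")] <- "fewer than 500 NN intervals"
  }

  data.frame(index = .index_names, value = unname(val),
             available = !is.na(unname(val)),
             reason = unname(reason), stringsAsFactors = FALSE)
}

#' Run the full pipeline for one subject
#'
#' Computes every computable index per condition (e.g. supine rest and
#' head-up tilt) from the per-condition NN series, plus baroreflex
#' sensitivity and LF coherency when a beat-domain systolic pressure series
#' is supplied. Unavailable indexes are explicit nulls with a reason.
#'
#' @param subject_id Subject identifier.
#' @param nn_by_condition Named list of [nn_series], one per condition.
#' @param sbp_by_condition Optional named list of SBP data frames
#'   (`time`, `value`), aligned with the conditions.
#' @param ... Passed to [hrv_indexes()].
#' @return A long data frame: `subject_id`, `condition`, `index`, `value`,
#'   `available`, `reason`.
#' @export
run_subject <- function(subject_id, nn_by_condition,
                        sbp_by_condition = NULL, ...) {
  if (is.null(names(nn_by_condition)) || any(names(nn_by_condition) == "")) {
    stop("nn_by_condition must be a named list of conditions")
  }
  out <- do.call(rbind, lapply(names(nn_by_condition), function(cond) {
    nn <- nn_by_condition[[cond]]
    rec <- hrv_indexes(nn, ...)
    if (!is.null(sbp_by_condition) && !is.null(sbp_by_condition[[cond]])) {
      br <- tryCatch(brs_from_beats(sbp_by_condition[[cond]], nn),
                     error = function(e) NULL)
      rec <- rbind(rec, data.frame(
        index = c("BRS", "LF_coherency"),
        value = if (is.null(br)) c(NA_real_, NA_real_)
                else c(br$brs, br$lf_coherency),
        available = !is.null(br),
        reason = if (is.null(br)) "SBP/NN overlap too short for transfer function"
                 else NA_character_,
        stringsAsFactors = FALSE
      ))
    }
    cbind(subject_id = subject_id, condition = cond, rec,
          stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

# Signal-level generator settings per group and condition, informed by the
# reference cohort: tachogram mean and band powers, plus a baroreflex gain
# used to synthesize a coupled SBP series.
.signal_params <- function(group, condition) {
  key <- paste(group, condition, sep = ".")
  p <- switch(key,
    "CNTR.SUP" = list(mean_nn = 922, nn_sd = 147, vlf = 1555, lf = 1258,
                      hf = 1087, brs = 13.97, brs_sd = 8.08),
    "CNTR.HUT" = list(mean_nn = 737, nn_sd = 104, vlf = 1188, lf = 1793,
                      hf = 336, brs = 8.66, brs_sd = 3.95),
    "T1DM.SUP" = list(mean_nn = 858, nn_sd = 104, vlf = 856, lf = 672,
                      hf = 459, brs = 11.65, brs_sd = 7.09),
    "T1DM.HUT" = list(mean_nn = 711, nn_sd = 99, vlf = 895, lf = 927,
                      hf = 201, brs = 6.80, brs_sd = 4.21),
    stop("unknown group/condition: ", key)
  )
  p
}

# moment-matched log-normal draw (positive, mean m, sd s)
.rlnorm_matched <- function(n, m, s) {
  s2 <- log(1 + (s / m)^2)
  rlnorm(n, meanlog = log(m) - s2 / 2, sdlog = sqrt(s2))
}

#' Simulate one subject's signals for a group and condition
#'
#' Draws subject-level tachogram parameters around the reference cohort
#' values (log-normal for powers, normal for the mean NN) and generates the
#' NN series with [generate_rr()] plus a linearly coupled beat-domain SBP
#' series whose baroreflex gain is drawn from the reference BRS
#' distribution.
#'
#' @param group `"CNTR"` or `"T1DM"`.
#' @param condition `"SUP"` or `"HUT"`.
#' @param duration_s Record length, seconds.
#' @param seed Integer seed.
#' @return A list with `nn` (an [nn_series]), `sbp` (data frame `time`,
#'   `value`) and `params` (the drawn subject parameters).
#' @export
simulate_subject <- function(group, condition, duration_s = 960, seed = 1) {
  p <- .signal_params(group, condition)
  set.seed(seed)
  mean_nn <- max(500, rnorm(1, p$mean_nn, p$nn_sd))
  powers <- c(vlf = .rlnorm_matched(1, p$vlf, 0.5 * p$vlf),
              lf = .rlnorm_matched(1, p$lf, 0.5 * p$lf),
              hf = .rlnorm_matched(1, p$hf, 0.5 * p$hf))
  hf_freq <- min(0.35, max(0.16, rnorm(1, 0.20, 0.03)))
  gain <- .rlnorm_matched(1, p$brs, p$brs_sd)
  cfg <- rr_model_config(
    duration_s = duration_s, mean_nn = mean_nn,
    vlf_power = powers[["vlf"]], lf_power = powers[["lf"]],
    hf_power = powers[["hf"]], hf_freq = hf_freq,
    noise_power = 0.1 * sum(powers), seed = seed + 1L
  )
  nn <- generate_rr(cfg)
  # SBP consistent with a linear baroreflex RR = mean + gain (SBP - mean):
  # invert the relation and add measurement noise
  sbp_vals <- 120 + (nn$intervals - mean(nn$intervals)) / gain +
    rnorm(length(nn$intervals), sd = 0.5)
  list(nn = nn,
       sbp = data.frame(time = nn$onset_times, value = sbp_vals),
       params = c(list(mean_nn = mean_nn, hf_freq = hf_freq, gain = gain),
                  as.list(powers)))
}

#' Run a seeded end-to-end synthetic cohort
#'
#' Simulates `n_per_group` subjects per group with per-condition signal
#' generation (supine rest and head-up tilt records), runs the full index
#' pipeline on every record, and produces the cohort index table, its
#' mean (SD) summary and the per-index ROC report. Optionally writes the
#' three tables as CSV files.
#'
#' @param n_per_group Subjects per group (>= 2).
#' @param seed Integer master seed (per-subject seeds derive from it).
#' @param durations Named record lengths in seconds per condition.
#' @param out_dir Optional directory for `cohort_table.csv`,
#'   `cohort_summary.csv` and `roc_report.csv`.
#' @param alpha Significance level for the ROC cut-off report.
#' @return A list with `records` (full long table including availability),
#'   `cohort` (available index values only, `cohort_table` layout),
#'   `summary` and `roc`.
#' @export
run_signal_cohort <- function(n_per_group = 20, seed = 1,
                              durations = c(SUP = 960, HUT = 600),
                              out_dir = NULL, alpha = 0.05) {
  if (n_per_group < 2) stop("need at least 2 subjects per group")
  set.seed(seed)
  subj_seeds <- sample.int(.Machine$integer.max - 10L,
                           2L * n_per_group * length(durations))
  k <- 0L
  records <- list()
  for (group in c("CNTR", "T1DM")) {
    for (i in seq_len(n_per_group)) {
      sid <- sprintf("%s_%03d", group, i)
      nns <- list(); sbps <- list()
      for (cond in names(durations)) {
        k <- k + 1L
        sim <- simulate_subject(group, cond,
                                duration_s = durations[[cond]],
                                seed = subj_seeds[k])
        nns[[cond]] <- sim$nn
        sbps[[cond]] <- sim$sbp
      }
      rec <- run_subject(sid, nns, sbps)
      rec$group <- group
      records[[sid]] <- rec
    }
  }
  records <- do.call(rbind, records)
  rownames(records) <- NULL
  cohort <- records[records$available & is.finite(records$value),
                    c("subject_id", "group", "condition", "index", "value")]
  class(cohort) <- c("cohort_table", "data.frame")
  summary <- summarize_cohort(cohort)
  roc <- roc_table(cohort, alpha = alpha)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(cohort, file.path(out_dir, "cohort_table.csv"),
              row.names = FALSE)
    write.csv(summary, file.path(out_dir, "cohort_summary.csv"),
              row.names = FALSE)
    write.csv(roc, file.path(out_dir, "roc_report.csv"), row.names = FALSE)
  }
  list(records = records, cohort = cohort, summary = summary, roc = roc)
}

#' Run an index-level synthetic cohort with ROC report
#'
#' Draws a cohort from configured index distributions and reports the
#' per-index ROC analysis in both conditions: the fast distribution-level
#' counterpart of [run_signal_cohort()].
#'
#' @param config A [cohort_config].
#' @param alpha Significance level for the ROC cut-off report.
#' @return A list with `cohort`, `summary` and `roc`.
#' @export
run_cohort <- function(config, alpha = 0.05) {
  cohort <- generate_cohort(config)
  list(cohort = cohort, summary = summarize_cohort(cohort),
       roc = roc_table(cohort, alpha = alpha))
}
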