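#' Reference distribution parameters of the study cohort
#'
#' Mean and SD of every HRV index per group (`CNTR` controls, `T1DM` type-1
#' diabetes) and condition (`SUP` supine rest, `HUT` head-up tilt), as
#' reported for the clinical cohort the package's synthetic module emulates.
#' These are the defaults of [cohort_config()].
#'
#' @return A data frame with columns `index`, `group`, `condition`, `mean`,
#'   `sd` and `unit`.
#' @export
table2_reference <- function() {
  # index, unit, CNTR SUP, CNTR HUT, T1DM SUP, T1DM HUT (mean, sd each)
  raw <- list(
    list("NNI_m",       "ms",   922,   147,   737,   104,   858,   104,   711,   99),
    list("pNN50+",      "%",    11.2,  9.2,   4.2,   4.7,   6.6,   7.3,   2.7,   3.2),
    list("pNN50-",      "%",    11.8,  9.8,   4.0,   4.6,   7.1,   8.7,   2.2,   3.3),
    list("RMSSD",       "ms",   50.5,  31.5,  28.5,  15.3,  33.1,  21.5,  21.6,  10.0),
    list("SDNN_i",      "ms",   62.1,  27.8,  58.0,  20.2,  44.4,  18.0,  45.9,  16.2),
    list("TOT_P",       "ms2",  4591,  4180,  3700,  2787,  2261,  1701,  2270,  1459),
    list("VLF",         "ms2",  1555,  1482,  1188,  517.4, 856,   547,   895,   536.9),
    list("LF",          "ms2",  1258,  1149,  1793,  2168,  672,   603.3, 927,   809.9),
    list("HF",          "ms2",  1087,  1741,  336,   331,   459,   633,   201,   200),
    list("LF_HF",       "",     2.03,  1.56,  6.58,  4.24,  2.45,  1.66,  6.48,  5.02),
    list("alpha_short", "",     0.817, 0.187, 1.089, 0.159, 0.898, 0.187, 1.108, 0.146),
    list("alpha_long",  "",     0.856, 0.175, 0.776, 0.218, 0.903, 0.140, 0.836, 0.167),
    list("SampEn",      "nats", 1.551, 0.332, 1.009, 0.323, 1.520, 0.293, 1.045, 0.336),
    list("MSE_HF",      "nats", 1.540, 0.194, 1.622, 0.264, 1.562, 0.204, 1.609, 0.227),
    list("MSE_LF",      "nats", 1.455, 0.254, 1.373, 0.162, 1.494, 0.188, 1.437, 0.232)
  )
  cells <- expand.grid(group = c("CNTR", "T1DM"), condition = c("SUP", "HUT"),
                       stringsAsFactors = FALSE)
  # column offsets in `raw` for (group, condition): CNTR SUP, CNTR HUT,
  # T1DM SUP, T1DM HUT
  off <- c("CNTR.SUP" = 3L, "CNTR.HUT" = 5L, "T1DM.SUP" = 7L, "T1DM.HUT" = 9L)
  out <- do.call(rbind, lapply(raw, function(row) {
    do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
      key <- paste(cells$group[i], cells$condition[i], sep = ".")
      data.frame(index = row[[1L]], group = cells$group[i],
                 condition = cells$condition[i],
                 mean = row[[off[[key]]]], sd = row[[off[[key]] + 1L]],
                 unit = row[[2L]], stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Configuration of a synthetic two-group, two-condition index cohort
#'
#' @param n_per_group Subjects per group (>= 2).
#' @param reference Data frame of per-index, per-group, per-condition `mean`
#'   and `sd` (defaults to [table2_reference()]).
#' @param indexes Optional character vector restricting generation to a
#'   subset of indexes; unknown names raise an error listing the known ones.
#' @param distribution `"gaussian"` or `"lognormal-matched"` (a log-normal
#'   with moments matched to the configured mean/SD, guaranteeing positive
#'   draws).
#' @param truncate For `"gaussian"` draws, clamp negative values to 0
#'   (default `FALSE`; clamping biases the sample moments for indexes whose
#'   SD is comparable to the mean).
#' @param seed Optional integer seed.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_per_group = 25, reference = table2_reference(),
                          indexes = NULL,
                          distribution = c("gaussian", "lognormal-matched"),
                          truncate = FALSE, seed = NULL) {
  distribution <- match.arg(distribution)
  if (n_per_group < 2) stop("invalid config: n_per_group must be at least 2")
  need <- c("index", "group", "condition", "mean", "sd")
  if (!all(need %in% names(reference))) {
    stop("reference must have columns ", paste(need, collapse = ", "))
  }
  if (any(reference$sd < 0)) stop("invalid config: SDs must be nonnegative")
  known <- unique(reference$index)
  if (!is.null(indexes)) {
    bad <- setdiff(indexes, known)
    if (length(bad)) {
      stop("unknown index name(s): ", paste(bad, collapse = ", "),
           "; known indexes: ", paste(known, collapse = ", "))
    }
    reference <- reference[reference$index %in% indexes, , drop = FALSE]
  }
  structure(
    list(n_per_group = n_per_group, reference = reference,
         distribution = distribution, truncate = truncate, seed = seed),
    class = "cohort_config"
  )
}

# One vector of n draws for a configured (mean, sd) cell.
.draw_index <- function(n, m, s, distribution, truncate) {
  if (s == 0) return(rep(m, n))
  if (distribution == "lognormal-matched") {
    if (m <= 0) stop("lognormal-matched requires positive means")
    s2 <- log(1 + (s / m)^2)
    return(rlnorm(n, meanlog = log(m) - s2 / 2, sdlog = sqrt(s2)))
  }
  x <- rnorm(n, mean = m, sd = s)
  if (truncate) x <- pmax(x, 0)
  x
}

#' Generate a synthetic index cohort
#'
#' Draws per-subject index values independently per index and condition from
#' the configured marginal distributions (no inter-index correlation: the
#' reference reports only marginals). Sample moments converge to the
#' configured mean/SD as `n_per_group` grows.
#'
#' @param config A [cohort_config].
#' @return A long-format data frame of class `cohort_table` with columns
#'   `subject_id`, `group`, `condition`, `index`, `value`.
#' @examples
#' ct <- generate_cohort(cohort_config(n_per_group = 5, seed = 1))
#' head(ct)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  ref <- config$reference
  n <- config$n_per_group
  ref <- ref[order(ref$index, ref$group, ref$condition), , drop = FALSE]
  out <- do.call(rbind, lapply(seq_len(nrow(ref)), function(i) {
    r <- ref[i, ]
    data.frame(
      subject_id = sprintf("%s_%03d", r$group, seq_len(n)),
      group = r$group, condition = r$condition, index = r$index,
      value = .draw_index(n, r$mean, r$sd, config$distribution,
                          config$truncate),
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' Summarize a cohort table as mean (SD) per index, group and condition
#'
#' @param cohort A `cohort_table` (long format, as produced by
#'   [generate_cohort()] or [run_signal_cohort()]).
#' @return A data frame with columns `index`, `group`, `condition`, `n`,
#'   `mean`, `sd`.
#' @export
summarize_cohort <- function(cohort) {
  need <- c("group", "condition", "index", "value")
  if (!all(need %in% names(cohort))) {
    stop("cohort must have columns ", paste(need, collapse = ", "))
  }
  agg <- aggregate(value ~ index + group + condition, data = cohort,
                   FUN = function(v) c(n = sum(is.finite(v)),
                                       mean = mean(v, na.rm = TRUE),
                                       sd = sd(v, na.rm = TRUE)))
  out <- data.frame(index = agg$index, group = agg$group,
                    condition = agg$condition,
                    n = agg$value[, "n"], mean = agg$value[, "mean"],
                    sd = agg$value[, "sd"], stringsAsFactors = FALSE)
  out[order(out$index, out$group, out$condition), ]
}
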