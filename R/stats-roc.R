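#' ROC area under the curve via the Mann-Whitney identity
#'
#' The AUC is the probability that a randomly chosen case scores on the
#' case side of a randomly chosen control (`direction = "case_low"`: cases
#' score lower), computed as U/(n1 n2) with midrank handling of ties. The
#' standard error uses the Hanley-McNeil formula by default (DeLong
#' available); the two-sided p-value against AUC = 0.5 comes from the
#' Mann-Whitney test (exact for small tie-free samples, normal
#' approximation otherwise).
#'
#' @param cases,controls Numeric index values per group (>= 2 each).
#' @param direction `"case_low"` (cases expected to score lower, the usual
#'   situation for depressed HRV indexes) or `"case_high"`.
#' @param se_method `"hanley"` (default) or `"delong"`.
#' @return A list of class `roc_result`: `auc`, `se`, `p`, `direction`,
#'   `n_cases`, `n_controls`.
#' @examples
#' roc_auc(cases = c(1, 2, 3), controls = c(2, 3, 4))$auc  # 0.778
#' @export
roc_auc <- function(cases, controls, direction = c("case_low", "case_high"),
                    se_method = c("hanley", "delong")) {
  direction <- match.arg(direction)
  se_method <- match.arg(se_method)
  cases <- as.numeric(cases); controls <- as.numeric(controls)
  if (length(cases) < 2L || length(controls) < 2L) {
    stop("need at least 2 values per group")
  }
  n1 <- as.numeric(length(cases)); n2 <- as.numeric(length(controls))
  # midrank AUC: P(case scores toward the case side of a control)
  r <- rank(c(cases, controls))
  w_cases <- sum(r[seq_len(n1)])
  auc_case_high <- (w_cases - n1 * (n1 + 1) / 2) / (n1 * n2)
  auc <- if (direction == "case_high") auc_case_high else 1 - auc_case_high
  se <- if (se_method == "hanley") {
    .auc_se_hanley(auc, n1, n2)
  } else {
    .auc_se_delong(cases, controls, direction)
  }
  p <- suppressWarnings(
    wilcox.test(cases, controls, alternative = "two.sided")$p.value
  )
  structure(
    list(auc = auc, se = se, p = p, direction = direction,
         n_cases = n1, n_controls = n2),
    class = "roc_result"
  )
}

.auc_se_hanley <- function(a, n1, n2) {
  q1 <- a / (2 - a)
  q2 <- 2 * a^2 / (1 + a)
  sqrt((a * (1 - a) + (n1 - 1) * (q1 - a^2) + (n2 - 1) * (q2 - a^2)) /
         (n1 * n2))
}

.auc_se_delong <- function(cases, controls, direction) {
  # placement-value covariance estimator
  side <- function(a, b) mean(a < b) + 0.5 * mean(a == b)
  if (direction == "case_high") {
    v10 <- vapply(cases, function(x) side(controls, x), numeric(1))
    v01 <- vapply(controls, function(y) side(y, cases), numeric(1))
  } else {
    v10 <- vapply(cases, function(x) side(x, controls), numeric(1))
    v01 <- vapply(controls, function(y) side(cases, y), numeric(1))
  }
  sqrt(var(v10) / length(cases) + var(v01) / length(controls))
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC %.3f (SE %.3f), p = %.3g [%s]\n",
              x$auc, x$se, x$p, x$direction))
  invisible(x)
}

#' Youden-index classification cut-off
#'
#' Scans the midpoints between adjacent pooled values and returns the
#' cut-off maximizing Youden's J = sensitivity + specificity - 1, breaking
#' ties toward higher specificity. Classification uses the strict
#' inequality in the case direction (e.g. "index < cutoff" flags a case
#' when `direction = "case_low"`).
#'
#' @inheritParams roc_auc
#' @return A list with `cutoff`, `sensitivity` (%), `specificity` (%) and
#'   `j`; all `NA` with a warning when the data are degenerate (a single
#'   pooled value).
#' @export
youden_cutoff <- function(cases, controls,
                          direction = c("case_low", "case_high")) {
  direction <- match.arg(direction)
  cases <- as.numeric(cases); controls <- as.numeric(controls)
  pooled <- sort(unique(c(cases, controls)))
  if (length(pooled) < 2L) {
    warning("degenerate data: Youden cut-off undefined")
    return(list(cutoff = NA_real_, sensitivity = NA_real_,
                specificity = NA_real_, j = NA_real_))
  }
  cand <- (head(pooled, -1) + tail(pooled, -1)) / 2
  stat <- vapply(cand, function(cut) {
    if (direction == "case_low") {
      sn <- mean(cases < cut); sp <- mean(controls >= cut)
    } else {
      sn <- mean(cases > cut); sp <- mean(controls <= cut)
    }
    c(sn, sp)
  }, numeric(2))
  j <- stat[1L, ] + stat[2L, ] - 1
  best <- which(j == max(j))
  if (length(best) > 1L) best <- best[which.max(stat[2L, best])]
  list(cutoff = cand[best], sensitivity = 100 * stat[1L, best],
       specificity = 100 * stat[2L, best], j = max(j))
}

#' Sensitivity/specificity of a cut-off under a normal model
#'
#' Model-based check of a printed cut-off: with case values ~ N(mean, sd)
#' and `direction = "case_low"`, the sensitivity of "value < cutoff" is
#' Phi((cutoff - mean)/sd). Used to link a reported distribution to a
#' reported cut-off sensitivity.
#'
#' @param cutoff Classification cut-off, index units.
#' @param mean,sd Normal model parameters of the scored group.
#' @param direction `"case_low"`: proportion below the cut-off;
#'   `"case_high"`: proportion above.
#' @return Proportion in `[0, 1]`.
#' @examples
#' normal_model_rate(57, mean = 44.4, sd = 18.0)  # 0.758
#' @export
normal_model_rate <- function(cutoff, mean, sd,
                              direction = c("case_low", "case_high")) {
  direction <- match.arg(direction)
  z <- (cutoff - mean) / sd
  if (direction == "case_low") pnorm(z) else pnorm(-z)
}

#' Pointwise two-group comparison of multiscale or spectral profiles
#'
#' At every abscissa of a common grid (frequency or scale), compares the
#' two groups with a two-sided Mann-Whitney test, reporting the U statistic
#' of the first group and significance masks at the 5% and 1% levels, with
#' an optional false-discovery-rate adjusted mask. Exact p-values are used
#' for small samples (normal approximation disabled below `exact_below`
#' subjects per group).
#'
#' @param profiles_a,profiles_b Numeric matrices, one row per subject, one
#'   column per grid point (>= 2 rows each; equal column counts).
#' @param grid Optional abscissa values (defaults to column index).
#' @param exact_below Use the exact U distribution when the smaller group
#'   has fewer subjects than this (default 8).
#' @param fdr Also compute Benjamini-Hochberg adjusted p-values.
#' @return A data frame with columns `grid`, `u`, `p`, `sig05`, `sig01`
#'   and, when `fdr = TRUE`, `p_adj` and `sig05_fdr`.
#' @export
pointwise_group_profile <- function(profiles_a, profiles_b, grid = NULL,
                                    exact_below = 8, fdr = FALSE) {
  profiles_a <- as.matrix(profiles_a); profiles_b <- as.matrix(profiles_b)
  if (ncol(profiles_a) != ncol(profiles_b)) {
    stop("profile grids differ: resample to a common grid first")
  }
  if (nrow(profiles_a) < 2L || nrow(profiles_b) < 2L) {
    stop("need at least 2 subjects per group")
  }
  if (is.null(grid)) grid <- seq_len(ncol(profiles_a))
  if (length(grid) != ncol(profiles_a)) stop("grid length mismatch")
  force_exact <- min(nrow(profiles_a), nrow(profiles_b)) < exact_below
  res <- vapply(seq_along(grid), function(j) {
    wt <- suppressWarnings(
      wilcox.test(profiles_a[, j], profiles_b[, j],
                  alternative = "two.sided",
                  exact = if (force_exact) TRUE else NULL)
    )
    c(unname(wt$statistic), wt$p.value)
  }, numeric(2))
  out <- data.frame(grid = grid, u = res[1L, ], p = res[2L, ],
                    sig05 = res[2L, ] < 0.05, sig01 = res[2L, ] < 0.01)
  if (fdr) {
    out$p_adj <- fdr_adjust(out$p)
    out$sig05_fdr <- out$p_adj < 0.05
  }
  out
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p-values; adjusted values are never smaller than the
#' raw ones and are monotone after sorting.
#'
#' @param pvalues Numeric p-values in `[0, 1]`.
#' @return Adjusted p-values, same order as the input.
#' @export
fdr_adjust <- function(pvalues) {
  pvalues <- as.numeric(pvalues)
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  p.adjust(pvalues, method = "BH")
}

#' Per-index ROC report for a cohort table
#'
#' Runs [roc_auc()] (T1DM as cases, CNTR as controls) for every index and
#' condition of a long-format cohort table and appends the Youden cut-off,
#' sensitivity and specificity when — and only when — the AUC is
#' significant at `alpha`.
#'
#' @param cohort A `cohort_table` data frame (`subject_id`, `group`,
#'   `condition`, `index`, `value`).
#' @param alpha Significance level gating the cut-off report (default 0.05).
#' @param directions Optional named character vector mapping index names to
#'   `"case_low"`/`"case_high"`; indexes default to `"case_low"` (reduced
#'   HRV in cases).
#' @param case_group,control_group Group labels.
#' @return A data frame with one row per index and condition: `auc`, `se`,
#'   `p`, `cutoff`, `sensitivity`, `specificity`, `direction`.
#' @export
roc_table <- function(cohort, alpha = 0.05, directions = NULL,
                      case_group = "T1DM", control_group = "CNTR") {
  need <- c("group", "condition", "index", "value")
  if (!all(need %in% names(cohort))) {
    stop("cohort must have columns ", paste(need, collapse = ", "))
  }
  cells <- unique(cohort[, c("index", "condition")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    idx <- cells$index[i]; cond <- cells$condition[i]
    sub <- cohort[cohort$index == idx & cohort$condition == cond, ]
    cases <- sub$value[sub$group == case_group]
    controls <- sub$value[sub$group == control_group]
    cases <- cases[is.finite(cases)]; controls <- controls[is.finite(controls)]
    if (length(cases) < 2L || length(controls) < 2L) return(NULL)
    dir <- if (!is.null(directions) && idx %in% names(directions)) {
      directions[[idx]]
    } else "case_low"
    rr <- roc_auc(cases, controls, direction = dir)
    row <- data.frame(index = idx, condition = cond, auc = rr$auc,
                      se = rr$se, p = rr$p, cutoff = NA_real_,
                      sensitivity = NA_real_, specificity = NA_real_,
                      direction = dir, stringsAsFactors = FALSE)
    if (is.finite(rr$p) && rr$p < alpha) {
      yc <- youden_cutoff(cases, controls, direction = dir)
      row$cutoff <- yc$cutoff
      row$sensitivity <- yc$sensitivity
      row$specificity <- yc$specificity
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
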