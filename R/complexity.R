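#' Sample entropy
#'
#' SampEn(m, r) = -ln(A/B), where B counts template pairs matching at length
#' `m` and A those also matching at length `m + 1`, using the Chebyshev
#' distance, excluding self-matches, with ties (distance exactly `r`)
#' counting as matches. Templates are the standard N - m overlapping vectors
#' so that every length-m template has an (m+1)-th point.
#'
#' @param x Numeric series (>= 50 points recommended; shorter input warns).
#' @param m Embedding dimension (default 1).
#' @param r Absolute tolerance; defaults to 15% of the SD of `x`.
#' @return Entropy in nats; `NA` with a warning when no matches exist at
#'   either length (undefined-entropy condition).
#' @examples
#' set.seed(1)
#' sampen(rnorm(1000))  # about 2.4 for white noise at r = 0.15 SD
#' @export
sampen <- function(x, m = 1, r = 0.15 * sd(x)) {
  x <- as.numeric(x)
  if (anyNA(x)) stop("x must not contain NA")
  if (length(x) < m + 2L) stop("series too short for embedding dimension m")
  if (length(x) < 50L) warning("fewer than 50 points: SampEn is unreliable")
  if (!is.finite(r) || r <= 0) stop("tolerance r must be positive")
  cnt <- sampen_counts(x, as.integer(m), r)
  if (cnt[["B"]] == 0 || cnt[["A"]] == 0) {
    warning("no template matches: sample entropy undefined")
    return(NA_real_)
  }
  -log(cnt[["A"]] / cnt[["B"]])
}

# Coarse-grained series at integer beat scale s.
.coarse_grain <- function(x, s, overlapping) {
  if (s == 1L) return(x)
  if (overlapping) {
    # stride-1 moving average of s consecutive values
    cs <- cumsum(c(0, x))
    (cs[(s + 1L):length(cs)] - cs[1:(length(cs) - s)]) / s
  } else {
    nb <- floor(length(x) / s)
    colMeans(matrix(x[1:(nb * s)], nrow = s))
  }
}

#' Multiscale entropy profile
#'
#' SampEn of the coarse-grained NN series as a function of the time scale
#' tau. At beat scale `s` the coarse-grained series is the moving average of
#' `s` consecutive NN intervals (stride 1 when `coarse_graining =
#' "overlapping"`, stride `s` otherwise); tau is `s` times the mean NN
#' interval in seconds. Under `tolerance_mode = "fixed_original_sd"` (the
#' default) the tolerance stays fixed at `r_frac` times the SD of the
#' original series at every scale.
#'
#' The `preset = "costa-replication"` shortcut selects the non-overlapping
#' coarse-graining with `m = 2` variant used in the classical multiscale
#' entropy literature.
#'
#' @param nn An [nn_series] with at least 250 intervals.
#' @param m Embedding dimension (default 1).
#' @param r_frac Tolerance as a fraction of the SD (default 0.15).
#' @param coarse_graining `"overlapping"` (default) or `"nonoverlapping"`.
#' @param tolerance_mode `"fixed_original_sd"` (default) or
#'   `"per_scale_sd"`.
#' @param max_tau_s Largest scale, seconds (default 25).
#' @param min_points Scales whose coarse-grained series has fewer points are
#'   dropped, truncating the profile with a warning.
#' @param preset Optional preset name overriding `m`, `coarse_graining` and
#'   `tolerance_mode`.
#' @return A [multiscale_profile] of kind `"mse"`.
#' @export
mse_profile <- function(nn, m = 1, r_frac = 0.15,
                        coarse_graining = c("overlapping", "nonoverlapping"),
                        tolerance_mode = c("fixed_original_sd",
                                           "per_scale_sd"),
                        max_tau_s = 25, min_points = 50,
                        preset = NULL) {
  stopifnot(inherits(nn, "nn_series"))
  if (!is.null(preset)) {
    preset <- match.arg(preset, "costa-replication")
    m <- 2
    coarse_graining <- "nonoverlapping"
    tolerance_mode <- "fixed_original_sd"
  }
  coarse_graining <- match.arg(coarse_graining)
  tolerance_mode <- match.arg(tolerance_mode)
  x <- nn$intervals
  if (length(x) < 250L) stop("need at least 250 NN intervals for MSE")
  mnn_s <- mean(x) / 1000
  r0 <- r_frac * sd(x)
  scales <- seq_len(max(1L, floor(max_tau_s / mnn_s)))
  vals <- numeric(0); taus <- numeric(0); used <- integer(0)
  truncated <- FALSE
  for (s in scales) {
    cg <- .coarse_grain(x, s, coarse_graining == "overlapping")
    if (length(cg) < min_points) { truncated <- TRUE; break }
    r_s <- if (tolerance_mode == "fixed_original_sd") r0 else r_frac * sd(cg)
    vals <- c(vals, suppressWarnings(sampen(cg, m = m, r = r_s)))
    taus <- c(taus, s * mnn_s)
    used <- c(used, s)
  }
  if (truncated) {
    warning("profile truncated: coarse-grained series shorter than ",
            min_points, " points beyond beat scale ", length(used))
  }
  multiscale_profile(taus, vals, used, kind = "mse")
}

# Unweighted mean of profile values with tau in [lo, hi) (or (lo, hi)).
.band_mean <- function(profile, lo, hi, closed_left = TRUE,
                       closed_right = FALSE) {
  sel <- (if (closed_left) profile$tau_s >= lo else profile$tau_s > lo) &
    (if (closed_right) profile$tau_s <= hi else profile$tau_s < hi)
  if (!any(sel)) return(NA_real_)
  mean(profile$values[sel])
}

#' Scale-band averages of a multiscale entropy profile
#'
#' Averages MSE(tau) over the scales corresponding to the HF
#' (2.5 <= tau < 6.7 s) and LF (6.7 <= tau < 25 s) spectral bands. Band
#' membership is decided by tau in seconds, not by beat count.
#'
#' @param profile A [multiscale_profile] of kind `"mse"`.
#' @param hf,lf Band limits in seconds (half-open).
#' @return A list with `mse_hf` and `mse_lf` (`NA` with a warning for an
#'   empty band).
#' @export
mse_bands <- function(profile, hf = c(2.5, 6.7), lf = c(6.7, 25)) {
  stopifnot(inherits(profile, "multiscale_profile"))
  out <- list(mse_hf = .band_mean(profile, hf[1L], hf[2L]),
              mse_lf = .band_mean(profile, lf[1L], lf[2L]))
  if (anyNA(out)) warning("empty MSE scale band: value undefined")
  out
}

# Fluctuation function F(n) of first-order DFA for one box size.
.dfa_fluct <- function(y, nbox, order) {
  nb <- floor(length(y) / nbox)
  Y <- matrix(y[1:(nb * nbox)], nrow = nbox)
  X <- outer(seq_len(nbox), 0:order, `^`)
  res <- qr.resid(qr(X), Y)
  sqrt(mean(res^2))
}

# Shared DFA machinery on a plain numeric series: log-spaced box grid,
# F(n), and the local slope alpha(n) by centered log-log differences.
.dfa_core <- function(x, min_box = 4, max_box = NULL,
                      points_per_octave = 8, order = 1) {
  n <- length(x)
  if (is.null(max_box)) max_box <- floor(n / 8)
  if (max_box <= min_box) stop("box range infeasible for series length")
  y <- cumsum(x - mean(x))
  grid <- unique(round(2^seq(log2(min_box), log2(max_box),
                             by = 1 / points_per_octave)))
  grid <- grid[grid >= order + 2]
  fl <- vapply(grid, function(b) .dfa_fluct(y, b, order), numeric(1))
  ok <- fl > 0
  grid <- grid[ok]; fl <- fl[ok]
  lf <- log(fl); lb <- log(grid)
  k <- length(grid)
  alpha <- numeric(k)
  if (k >= 2L) {
    alpha[1L] <- (lf[2L] - lf[1L]) / (lb[2L] - lb[1L])
    alpha[k] <- (lf[k] - lf[k - 1L]) / (lb[k] - lb[k - 1L])
    if (k > 2L) {
      alpha[2:(k - 1L)] <- (lf[3:k] - lf[1:(k - 2L)]) /
        (lb[3:k] - lb[1:(k - 2L)])
    }
  }
  list(boxes = grid, fluct = fl, alpha = alpha)
}

#' Multiscale detrended fluctuation analysis profile
#'
#' Integrates the mean-removed NN series, computes the first-order DFA
#' fluctuation function F(n) over a log-spaced grid of box sizes
#' (non-overlapping boxes, piecewise polynomial detrending), and estimates
#' the scale-dependent self-similarity coefficient alpha(tau) as the local
#' slope of log F vs log n by centered finite differences (one-sided at the
#' edges). tau maps beat scale to seconds through the mean NN interval.
#'
#' @param nn An [nn_series] with at least 500 intervals.
#' @param min_box,max_box Box-size range in beats (defaults 4 to n/8).
#' @param points_per_octave Box-grid density (default 8).
#' @param order Detrending polynomial order (default 1, standard DFA-1).
#' @return A [multiscale_profile] of kind `"alpha"`, with the fluctuation
#'   function attached as attribute `fluct`.
#' @export
mdfa_profile <- function(nn, min_box = 4, max_box = NULL,
                         points_per_octave = 8, order = 1) {
  stopifnot(inherits(nn, "nn_series"))
  x <- nn$intervals
  if (length(x) < 500L) stop("need at least 500 NN intervals for DFA")
  core <- .dfa_core(x, min_box, max_box, points_per_octave, order)
  mnn_s <- mean(x) / 1000
  prof <- multiscale_profile(core$boxes * mnn_s, core$alpha, core$boxes,
                             kind = "alpha")
  attr(prof, "fluct") <- core$fluct
  prof
}

#' Global DFA scaling exponent
#'
#' Least-squares slope of log F(n) against log n over the whole box grid:
#' the classical single-exponent DFA estimate (0.5 for white noise, 1.5 for
#' integrated white noise).
#'
#' @param x Numeric series (e.g. NN intervals or a surrogate).
#' @inheritParams mdfa_profile
#' @return The scaling exponent alpha-hat.
#' @export
dfa_exponent <- function(x, min_box = 4, max_box = NULL,
                         points_per_octave = 8, order = 1) {
  core <- .dfa_core(as.numeric(x), min_box, max_box, points_per_octave,
                    order)
  unname(coef(lm(log(core$fluct) ~ log(core$boxes)))[2L])
}

#' Scale-band averages of a DFA profile
#'
#' The short-term coefficient averages alpha(tau) over 5 <= tau <= 11 s;
#' the long-term coefficient over 17 < tau < 61 s.
#'
#' @param profile A [multiscale_profile] of kind `"alpha"`.
#' @param short Closed short-scale band, seconds.
#' @param long Open long-scale band, seconds.
#' @return A list with `alpha_short` and `alpha_long` (`NA` with a warning
#'   when a band is not covered).
#' @export
alpha_bands <- function(profile, short = c(5, 11), long = c(17, 61)) {
  stopifnot(inherits(profile, "multiscale_profile"))
  out <- list(
    alpha_short = .band_mean(profile, short[1L], short[2L],
                             closed_left = TRUE, closed_right = TRUE),
    alpha_long = .band_mean(profile, long[1L], long[2L],
                            closed_left = FALSE, closed_right = FALSE)
  )
  if (anyNA(out)) warning("DFA profile does not cover a scale band")
  out
}
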