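#' Configuration for the synthetic RR-tachogram generator
#'
#' Describes an RR (NN) interval series as a mean level plus one sinusoidal
#' oscillator per spectral band (VLF, LF, HF) and a broadband 1/f^beta
#' Gaussian background. Powers are the target band powers of the 5-Hz
#' resampled tachogram as estimated by [welch_psd()]; the generator
#' pre-compensates the oscillator amplitudes for the attenuation introduced
#' by linear interpolation of a beat-rate-sampled sinusoid.
#'
#' @param duration_s Record length, seconds (> 0).
#' @param mean_nn Mean NN interval, ms (> 0).
#' @param vlf_power,lf_power,hf_power Oscillator band powers, ms^2 (>= 0).
#' @param vlf_freq,lf_freq,hf_freq Oscillator frequencies, Hz. When used to
#'   place oscillators in-band: 0.005 <= vlf_freq < 0.04 <= lf_freq < 0.15
#'   <= hf_freq < 0.40.
#' @param noise_power Variance of the broadband 1/f^beta background, ms^2.
#' @param noise_beta Spectral slope of the background (default 1, matching
#'   the near-1/f self-similarity of resting heart rate).
#' @param seed Optional integer seed for reproducibility.
#' @return A list of class `rr_model_config`.
#' @export
rr_model_config <- function(duration_s = 960, mean_nn = 900,
                            vlf_power = 0, lf_power = 0, hf_power = 0,
                            vlf_freq = 0.02, lf_freq = 0.10, hf_freq = 0.25,
                            noise_power = 0, noise_beta = 1, seed = NULL) {
  if (duration_s <= 0) stop("invalid config: duration_s must be positive")
  if (mean_nn <= 0) stop("invalid config: mean_nn must be positive")
  pw <- c(vlf_power, lf_power, hf_power, noise_power)
  if (any(pw < 0)) stop("invalid config: powers must be nonnegative")
  if (!(lf_freq < hf_freq)) stop("invalid config: lf_freq must be below hf_freq")
  structure(
    list(duration_s = duration_s, mean_nn = mean_nn,
         vlf_power = vlf_power, lf_power = lf_power, hf_power = hf_power,
         vlf_freq = vlf_freq, lf_freq = lf_freq, hf_freq = hf_freq,
         noise_power = noise_power, noise_beta = noise_beta, seed = seed),
    class = "rr_model_config"
  )
}

# Gaussian 1/f^beta background, standardized to the requested SD.
.one_over_f <- function(n, beta, sd_target) {
  if (sd_target <= 0) return(numeric(n))
  white <- fft(rnorm(n))
  k <- seq_len(n) - 1L
  fidx <- pmin(k, n - k)            # symmetric frequency index
  shape <- ifelse(fidx == 0, 0, fidx^(-beta / 2))
  x <- Re(fft(white * shape, inverse = TRUE)) / n
  x / sd(x) * sd_target
}

# Attenuation of a sinusoid at frequency f (Hz) sampled once per beat of
# mean length mean_nn (ms) and linearly interpolated: sinc^2(f * T_beat).
.lin_interp_gain <- function(f, mean_nn) {
  u <- f * mean_nn / 1000
  ifelse(u == 0, 1, (sin(pi * u) / (pi * u))^2)
}

#' Generate a synthetic NN-interval series
#'
#' Samples the configured oscillators and 1/f background at the beat onsets
#' (beat-domain generation: the next beat time is advanced by the current NN
#' interval), producing an [nn_series] whose Welch band powers match the
#' configured powers. Deterministic under a fixed seed.
#'
#' @param config An [rr_model_config].
#' @return An [nn_series].
#' @examples
#' nn <- generate_rr(rr_model_config(duration_s = 960, mean_nn = 900,
#'                                   hf_power = 900, seed = 1))
#' band_powers(welch_psd(resample_nn(nn)))$hf
#' @export
generate_rr <- function(config) {
  stopifnot(inherits(config, "rr_model_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  freqs <- c(config$vlf_freq, config$lf_freq, config$hf_freq)
  powers <- c(config$vlf_power, config$lf_power, config$hf_power)
  amps <- sqrt(2 * powers) / .lin_interp_gain(freqs, config$mean_nn)
  phases <- runif(3, 0, 2 * pi)
  n_max <- ceiling(config$duration_s * 1000 / (0.4 * config$mean_nn)) + 8L
  noise <- .one_over_f(n_max, config$noise_beta, sqrt(config$noise_power))
  nn <- numeric(n_max)
  onset <- numeric(n_max)
  t <- 0; i <- 0L
  while (t < config$duration_s && i < n_max) {
    i <- i + 1L
    v <- config$mean_nn +
      sum(amps * sin(2 * pi * freqs * t + phases)) + noise[i]
    v <- max(v, 250)                 # physiological floor
    nn[i] <- v
    onset[i] <- t
    t <- t + v / 1000
  }
  nn_series(nn[1:i], onset[1:i])
}

#' Generate a synthetic single-lead ECG from beat times
#'
#' Places one Gaussian QRS template at each beat time, with the QRS amplitude
#' modulated by a respiratory sinusoid:
#' `amp(t) = 1 + resp_mod_depth * sin(2 pi resp_freq t)`. The sample closest
#' to each beat time is the local maximum, so detector ground truth is the
#' input beat times.
#'
#' @param beat_times Strictly increasing beat times, seconds.
#' @param resp_freq Respiratory modulation frequency, Hz.
#' @param resp_mod_depth Fractional modulation depth in `[0, 1)`.
#' @param fs Sampling frequency, Hz (>= 250).
#' @param qrs_sd Width (SD) of the Gaussian QRS template, seconds.
#' @param noise_sd Additive white measurement noise SD (template units).
#' @param duration_s Optional record length, seconds (defaults to half a
#'   second past the last beat).
#' @param seed Optional integer seed (only used when `noise_sd > 0`).
#' @return An [ecg_record].
#' @export
generate_ecg <- function(beat_times, resp_freq = 0.25, resp_mod_depth = 0.2,
                         fs = 1000, qrs_sd = 0.01, noise_sd = 0,
                         duration_s = NULL, seed = NULL) {
  beat_times <- as.numeric(beat_times)
  if (length(beat_times) < 1L) stop("need at least one beat time")
  if (length(beat_times) > 1L && any(diff(beat_times) <= 0)) {
    stop("beat times must be strictly increasing")
  }
  if (fs < 250) stop("fs must be at least 250 Hz")
  if (resp_mod_depth < 0 || resp_mod_depth >= 1) {
    stop("resp_mod_depth must be in [0, 1)")
  }
  if (!is.null(seed)) set.seed(seed)
  duration <- if (is.null(duration_s)) max(beat_times) + 0.5 else duration_s
  if (duration < max(beat_times)) stop("duration_s ends before the last beat")
  n <- ceiling(duration * fs) + 1L
  x <- numeric(n)
  hw <- ceiling(4 * qrs_sd * fs)     # template half-width, samples
  for (tb in beat_times) {
    amp <- 1 + resp_mod_depth * sin(2 * pi * resp_freq * tb)
    kc <- round(tb * fs) + 1L
    ks <- max(1L, kc - hw):min(n, kc + hw)
    tt <- (ks - 1L) / fs
    x[ks] <- x[ks] + amp * exp(-(tt - tb)^2 / (2 * qrs_sd^2))
  }
  if (noise_sd > 0) x <- x + rnorm(n, sd = noise_sd)
  ecg_record(x, fs = fs)
}

#' Configuration for baroreflex-coupled SBP/RR generation
#'
#' A systolic pressure series carrying an LF sinusoid drives the RR interval
#' through a linear baroreflex with known gain and delay, plus Gaussian RR
#' noise: `RR = mean_nn + gain * (SBP(t - delay) - sbp_mean) + noise`.
#'
#' @param gain Baroreflex gain, ms/mmHg (>= 0).
#' @param delay_s Reflex delay, seconds.
#' @param sbp_lf_amplitude Amplitude of the SBP LF oscillation, mmHg.
#' @param sbp_lf_freq LF oscillation frequency, Hz (0.04-0.15 for LF-band
#'   validation).
#' @param rr_noise_sd SD of additive Gaussian RR noise, ms.
#' @param sbp_noise_sd SD of broadband beat-to-beat SBP variability, mmHg
#'   (coupled to RR through the same reflex gain; gives the SBP spectrum a
#'   realistic noise floor outside the LF oscillation).
#' @param sbp_mean Mean systolic pressure, mmHg.
#' @param mean_nn Mean NN interval, ms.
#' @param seed Optional integer seed.
#' @return A list of class `baro_coupling_config`.
#' @export
baro_coupling_config <- function(gain = 10, delay_s = 0.5,
                                 sbp_lf_amplitude = 10, sbp_lf_freq = 0.10,
                                 rr_noise_sd = 0, sbp_noise_sd = 1,
                                 sbp_mean = 120, mean_nn = 900,
                                 seed = NULL) {
  if (gain < 0) stop("invalid config: gain must be nonnegative")
  if (sbp_lf_freq <= 0) stop("invalid config: sbp_lf_freq must be positive")
  if (rr_noise_sd < 0 || sbp_noise_sd < 0) {
    stop("invalid config: noise SDs must be nonnegative")
  }
  if (mean_nn <= 0) stop("invalid config: mean_nn must be positive")
  structure(
    list(gain = gain, delay_s = delay_s,
         sbp_lf_amplitude = sbp_lf_amplitude, sbp_lf_freq = sbp_lf_freq,
         rr_noise_sd = rr_noise_sd, sbp_noise_sd = sbp_noise_sd,
         sbp_mean = sbp_mean, mean_nn = mean_nn, seed = seed),
    class = "baro_coupling_config"
  )
}

#' Generate a baroreflex-coupled SBP and NN pair
#'
#' @param config A [baro_coupling_config].
#' @param duration_s Record length, seconds. Durations shorter than two
#'   Welch windows (240 s) trigger a warning: spectral estimates of the
#'   coupling become unreliable.
#' @return A list with `sbp` (data frame `time`, `value`: beat-domain
#'   systolic pressure, mmHg) and `nn` (an [nn_series]).
#' @export
generate_coupled_sbp_rr <- function(config, duration_s = 960) {
  stopifnot(inherits(config, "baro_coupling_config"))
  if (duration_s <= 0) stop("duration_s must be positive")
  if (duration_s < 240) {
    warning("duration shorter than two Welch windows (240 s): ",
            "spectral estimates will be unreliable")
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  lf_at <- function(t) {
    config$sbp_lf_amplitude * sin(2 * pi * config$sbp_lf_freq * t)
  }
  n_max <- ceiling(duration_s * 1000 / (0.4 * config$mean_nn)) + 8L
  rr_noise <- if (config$rr_noise_sd > 0) {
    rnorm(n_max, sd = config$rr_noise_sd)
  } else numeric(n_max)
  sbp_noise <- if (config$sbp_noise_sd > 0) {
    rnorm(n_max, sd = config$sbp_noise_sd)
  } else numeric(n_max)
  nn <- numeric(n_max); onset <- numeric(n_max); sbp <- numeric(n_max)
  t <- 0; i <- 0L
  while (t < duration_s && i < n_max) {
    i <- i + 1L
    sbp[i] <- config$sbp_mean + lf_at(t) + sbp_noise[i]
    # the reflex delay acts on the LF oscillation; the broadband pressure
    # variability couples within the same beat
    v <- config$mean_nn +
      config$gain * (lf_at(t - config$delay_s) + sbp_noise[i]) + rr_noise[i]
    v <- max(v, 250)
    nn[i] <- v
    onset[i] <- t
    t <- t + v / 1000
  }
  list(
    sbp = data.frame(time = onset[1:i], value = sbp[1:i]),
    nn = nn_series(nn[1:i], onset[1:i])
  )
}
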