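test_that("R-peak detection is exact on clean synthetic ECG, 40-180 bpm", {
  for (bpm in c(40, 80, 180)) {
    beats_t <- seq(0, 120, by = 60 / bpm)
    ecg <- generate_ecg(beats_t, resp_mod_depth = 0.2, fs = 1000)
    det <- detect_r_peaks(ecg)
    expect_equal(length(det$times), length(beats_t))   # recall & precision 1
    expect_lt(max(abs(det$times - beats_t)), 0.002)    # within 2 ms
  }
})

test_that("a single QRS in 10 s of silence yields exactly one peak", {
  ecg <- generate_ecg(5, resp_mod_depth = 0, fs = 500, duration_s = 10)
  det <- detect_r_peaks(ecg)
  expect_equal(length(det$times), 1L)
  expect_equal(det$times, 5, tolerance = 1e-3)
})

test_that("parabolic refinement is symmetric and bounded", {
  # on-grid apex of a symmetric template: vertex offset must be 0
  ecg <- generate_ecg(c(5, 6.5, 8, 9.5, 11, 12.5), resp_mod_depth = 0,
                      fs = 250, duration_s = 15)
  det <- detect_r_peaks(ecg)
  expect_equal(det$times, c(5, 6.5, 8, 9.5, 11, 12.5), tolerance = 1e-9)
})

test_that("all-constant ECG gives an empty series with a warning", {
  expect_warning(det <- detect_r_peaks(ecg_record(rep(1, 20 * 250), 250)),
                 "constant")
  expect_equal(length(det$times), 0L)
})

test_that("cleaning drops a premature beat and its compensatory pause", {
  b <- beat_series(cumsum(c(0, 800, 810, 400, 1200, 805, 795)) / 1000)
  nn <- clean_to_nn(b)
  expect_equal(nn$intervals, c(800, 810, 805, 795))
  expect_equal(nn$contiguous, c(FALSE, TRUE, FALSE, TRUE))  # gap flagged
})

test_that("cleaning is the identity on a steady all-normal series", {
  rr <- rep(820, 60) + rep(c(-10, 10), 30)
  b <- beat_series(cumsum(c(0, rr)) / 1000)
  nn <- clean_to_nn(b)
  expect_equal(nn$intervals, rr)
  expect_true(all(nn$contiguous[-1L]))
})

test_that("pathological alternating series leaves no contiguous pairs", {
  rr <- rep(c(400, 1200), 50)
  b <- beat_series(cumsum(c(0, rr)) / 1000)
  res <- tryCatch(clean_to_nn(b), error = function(e) e)
  if (inherits(res, "error")) {
    expect_match(conditionMessage(res), "fewer than 2")
  } else {
    expect_equal(sum(res$contiguous), 0L)   # signaled: every pair gapped
  }
})

test_that("cleaning its own output changes nothing", {
  set.seed(7)
  rr <- pmax(400, rnorm(200, 850, 40))
  # one premature beat + compensatory pause, one missed-beat gap; the
  # merged spans around the rejected beats re-trigger the long-interval
  # rule on reapplication
  rr[c(50, 51)] <- c(400, 1200)
  rr[120] <- 2000
  nn1 <- clean_to_nn(beat_series(cumsum(c(0, rr)) / 1000))
  nn2 <- clean_to_nn(nn_to_beats(nn1))
  expect_equal(nn2$intervals, nn1$intervals)
})

test_that("input beat labels and overrides exclude adjacent intervals", {
  rr <- rep(800, 10)
  b <- beat_series(cumsum(c(0, rr)) / 1000,
                   labels = c(rep("normal", 5), "artifact", rep("normal", 5)))
  nn <- clean_to_nn(b)
  expect_equal(length(nn$intervals), 8L)    # two intervals touching beat 6 gone
  nn_ov <- clean_to_nn(beat_series(cumsum(c(0, rr)) / 1000),
                       override_artifact = 6L)
  expect_equal(nn_ov$intervals, nn$intervals)
})

test_that("mean NN interval is the arithmetic mean", {
  expect_equal(mean_nn(nn_series(c(800, 900))), 850)
  expect_equal(mean_nn(nn_series(rep(922, 100))), 922)
  expect_equal(mean_nn(nn_series(750)), 750)
})

test_that("EDR recovers the respiratory modulation frequency", {
  beats_t <- seq(0, 599, by = 1)
  ecg <- generate_ecg(beats_t, resp_freq = 0.25, resp_mod_depth = 0.2,
                      fs = 250)
  det <- detect_r_peaks(ecg)
  expect_lt(abs(edr(det) - 0.25), 0.01)
})

test_that("EDR rejects sub-cutoff modulation and flags flat amplitudes", {
  beats_t <- seq(0, 599, by = 1)
  ecg <- generate_ecg(beats_t, resp_freq = 0.03, resp_mod_depth = 0.2,
                      fs = 250)
  f <- edr(detect_r_peaks(ecg))
  expect_false(isTRUE(all.equal(f, 0.03, tolerance = 0.005)))
  flat <- detect_r_peaks(generate_ecg(beats_t, resp_mod_depth = 0, fs = 250))
  expect_warning(f0 <- edr(flat), "undefined")
  expect_true(is.na(f0))
})

test_that("EDR is invariant to global amplitude scaling", {
  beats_t <- seq(0, 299, by = 0.9)
  ecg <- generate_ecg(beats_t, resp_freq = 0.2, resp_mod_depth = 0.3,
                      fs = 250)
  det <- detect_r_peaks(ecg)
  scaled <- beat_series(det$times, det$amplitudes * 37)
  expect_equal(edr(det), edr(scaled))
})
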