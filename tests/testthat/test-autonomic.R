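# windowed extremum-minus-baseline contracts of the autonomic test battery

test_that("deep breathing heart-rate range converts units correctly", {
  nn <- nn_series(rep(c(800, 1000), 20))   # HR swings 75 <-> 60 bpm
  expect_equal(deep_breathing_dhr(nn, c(0, 40)), 15)
  expect_equal(deep_breathing_dhr(nn_series(rep(800, 40)), c(0, 30)), 0)
  expect_error(deep_breathing_dhr(nn, c(100, 110)), "empty")
})

test_that("paced-breathing synthetic gives a physiological HR range", {
  # 6 breaths/min (0.1 Hz, in the LF range) with 20% NN modulation
  nn <- generate_rr(rr_model_config(duration_s = 120, mean_nn = 900,
                                    lf_power = (0.2 * 900)^2 / 2,
                                    lf_freq = 0.1, seed = 41))
  dhr <- deep_breathing_dhr(nn, c(10, 110))
  expect_gt(dhr, 10)
  expect_lt(dhr, 35)
})

test_that("Valsalva ratio takes the best maneuver", {
  rr <- c(rep(800, 10), rep(500, 10), rep(1000, 10), rep(800, 10))
  onset <- cumsum(c(0, rr[-length(rr)])) / 1000
  nn <- nn_series(rr, onset)
  m1 <- list(phase2 = c(8, 13), phase4 = c(13, 21))
  expect_equal(valsalva_ratio(nn, list(m1)), 2.0)
  # three maneuvers, max rule: scale phase IV peaks
  flat <- nn_series(rep(800, 60))
  expect_equal(valsalva_ratio(flat, list(list(phase2 = c(0, 10),
                                              phase4 = c(10, 20)))), 1.0)
  expect_warning(
    r <- valsalva_ratio(nn, list(m1, list(phase2 = c(200, 210),
                                          phase4 = c(210, 220)))),
    "skipped")
  expect_equal(r, 2.0)
  expect_error(
    suppressWarnings(valsalva_ratio(nn, list(list(phase2 = c(200, 210),
                                                  phase4 = c(210, 220))))),
    "all maneuvers")
})

test_that("handgrip response is max grip DBP minus mean baseline", {
  dbp <- data.frame(time = 0:199,
                    value = c(rep(80, 100), seq(80, 102, length.out = 100)))
  expect_equal(handgrip_ddbp(dbp, c(0, 100), c(100, 200)), 22)
  flat <- data.frame(time = 0:199, value = rep(85, 200))
  expect_equal(handgrip_ddbp(flat, c(0, 100), c(100, 200)), 0)
  drop <- data.frame(time = 0:199, value = c(rep(80, 100), rep(70, 100)))
  expect_equal(handgrip_ddbp(drop, c(0, 100), c(100, 200)), -10)
})

test_that("30:15 ratio compares the post-tilt RR extrema windows", {
  rr <- c(rep(800, 50), rep(600, 20), rep(900, 30))  # dip then recovery
  onset <- cumsum(c(0, rr[-length(rr)])) / 1000
  nn <- nn_series(rr, onset)
  tilt <- onset[51]
  expect_gt(hut_3015(nn, tilt), 1)
  expect_equal(hut_3015(nn, tilt), 900 / 600)
  const <- nn_series(rep(800, 120))
  expect_equal(hut_3015(const, 10), 1.0)
  expect_error(hut_3015(const, 90), "40 beats")
})

test_that("tilt SBP fall keeps the sign convention", {
  sbp <- data.frame(time = 0:299,
                    value = c(rep(120, 120), rep(111, 60), rep(118, 120)))
  expect_equal(hut_dsbp(sbp, baseline_window = c(0, 120), tilt_start = 120),
               -9)
})

test_that("cold pressor windows are clamped to the immersion duration", {
  dbp <- data.frame(time = 0:299,
                    value = c(rep(80, 100), rep(95, 90), rep(120, 110)))
  expect_warning(
    d <- cold_pressor_ddbp(dbp, c(0, 100), c(100, 250)),
    "clamped")
  expect_equal(d, 15)   # the 120-mmHg values after 90 s are ignored
  nn <- nn_series(rep(800, 300))
  expect_equal(cold_pressor_dhr(nn, c(0, 100), c(100, 190)), 0)
})

test_that("Ewing scoring is the thresholded sum over five tests", {
  normal <- list(deep_breathing = 20, valsalva = 1.8, handgrip = 20,
                 hut_3015 = 1.2, hut_dsbp = -5)
  expect_equal(ewing_score(normal), 0)
  abnormal <- list(deep_breathing = 5, valsalva = 1.0, handgrip = 5,
                   hut_3015 = 0.95, hut_dsbp = -40)
  expect_equal(ewing_score(abnormal), 5)
  mixed <- list(deep_breathing = 12, valsalva = 1.15, handgrip = 5,
                hut_3015 = 1.2, hut_dsbp = -5)
  expect_equal(ewing_score(mixed), 2.0)   # 0.5 + 0.5 + 1
  expect_error(ewing_score(normal[-2]), "valsalva")
})

test_that("Ewing score is monotone as one outcome deteriorates", {
  base <- list(deep_breathing = 20, valsalva = 1.8, handgrip = 20,
               hut_3015 = 1.2, hut_dsbp = -5)
  scores <- vapply(c(20, 12, 5), function(v) {
    base$deep_breathing <- v
    ewing_score(base)
  }, numeric(1))
  expect_equal(scores, c(0, 0.5, 1))
  expect_true(all(diff(scores) >= 0))
})

test_that("SCOPA-AUT score is a linear percentage of the maximum", {
  expect_equal(scopa_score(rep(0, 23)), 0)
  expect_equal(scopa_score(rep(3, 23)), 100)
  items <- rep(0, 23); items[1:5] <- 1
  expect_equal(scopa_score(items), 100 * 5 / 69)
  expect_equal(scopa_score(2 * items) , 2 * scopa_score(items))
  # the score is reported as a percentage of the achievable maximum
  frac <- scopa_score(c(rep(1, 5), rep(0, 18)))
  expect_equal(frac, 7.2, tolerance = 0.01)
})

test_that("SCOPA-AUT missing-item policy prorates or errors", {
  items <- rep(1, 23); items[4] <- NA
  expect_equal(scopa_score(items), 100 * 22 / 66)
  expect_error(scopa_score(items, missing = "error"), "missing")
  bad <- rep(1, 23); bad[1] <- 5
  expect_error(scopa_score(bad), "out of range")
})
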