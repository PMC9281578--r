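test_that("generate_rr is deterministic under a fixed seed", {
  cfg <- rr_model_config(duration_s = 300, mean_nn = 850, lf_power = 400,
                         hf_power = 300, noise_power = 200, seed = 42)
  a <- generate_rr(cfg)
  b <- generate_rr(cfg)
  expect_identical(a, b)
  c2 <- generate_rr(rr_model_config(duration_s = 300, mean_nn = 850,
                                    lf_power = 400, hf_power = 300,
                                    noise_power = 200, seed = 43))
  expect_false(identical(a$intervals, c2$intervals))
})

test_that("generate_rr with all powers zero yields a constant series", {
  nn <- generate_rr(rr_model_config(duration_s = 120, mean_nn = 800))
  expect_true(all(nn$intervals == 800))
  expect_equal(diff(nn$onset_times), rep(0.8, length(nn) - 1L))
})

test_that("generated band powers match the configured oscillator powers", {
  nn <- generate_rr(rr_model_config(duration_s = 960, mean_nn = 900,
                                    hf_power = 900, hf_freq = 0.25,
                                    seed = 1))
  bp <- band_powers(welch_psd(resample_nn(nn)))
  expect_lt(abs(bp$hf - 900) / 900, 0.10)
  expect_lt(bp$lf, 0.05 * bp$hf)
})

test_that("invalid RR configs are rejected", {
  expect_error(rr_model_config(duration_s = 0), "duration_s")
  expect_error(rr_model_config(mean_nn = -5), "mean_nn")
  expect_error(rr_model_config(hf_power = -1), "powers")
})

test_that("generate_ecg places modulated QRS maxima at the beat times", {
  beats_t <- seq(0, 59, by = 1)
  ecg <- generate_ecg(beats_t, resp_freq = 0.25, resp_mod_depth = 0.2,
                      fs = 500)
  for (tb in beats_t[c(1, 20, 45)]) {
    k <- round(tb * 500) + 1L
    win <- max(1, k - 100):min(length(ecg$samples), k + 100)
    expect_equal(win[which.max(ecg$samples[win])], k)
  }
  # depth 0: all QRS amplitudes equal
  flat <- generate_ecg(beats_t, resp_mod_depth = 0, fs = 500)
  apex <- flat$samples[round(beats_t * 500) + 1L]
  expect_equal(max(apex) - min(apex), 0, tolerance = 1e-12)
  expect_error(generate_ecg(c(1, 1, 2)), "increasing")
  expect_error(generate_ecg(beats_t, fs = 100), "250")
})

test_that("coupled SBP/RR generator obeys its contracts", {
  expect_warning(
    generate_coupled_sbp_rr(baro_coupling_config(seed = 1), duration_s = 120),
    "240"
  )
  cfg <- baro_coupling_config(gain = 5, rr_noise_sd = 3, seed = 9)
  a <- generate_coupled_sbp_rr(cfg, 300)
  b <- generate_coupled_sbp_rr(cfg, 300)
  expect_identical(a, b)
  expect_error(baro_coupling_config(gain = -1), "gain")
})

test_that("cohort sample moments converge to the configured reference", {
  ct <- generate_cohort(cohort_config(n_per_group = 40000,
                                      indexes = "RMSSD", seed = 3))
  v <- ct$value[ct$group == "CNTR" & ct$condition == "SUP"]
  expect_lt(abs(mean(v) - 50.5) / 50.5, 0.01)
  expect_lt(abs(sd(v) - 31.5) / 31.5, 0.02)
})

test_that("cohort generator handles degenerate and small configs", {
  ref <- table2_reference()
  ref$sd[ref$index == "RMSSD"] <- 0
  ct <- generate_cohort(cohort_config(n_per_group = 5, reference = ref,
                                      indexes = "RMSSD", seed = 1))
  sup <- ct[ct$condition == "SUP" & ct$group == "CNTR", ]
  expect_true(all(sup$value == sup$value[1L]))

  ct2 <- generate_cohort(cohort_config(n_per_group = 2, indexes = "SDNN_i",
                                       seed = 1))
  sup2 <- ct2[ct2$condition == "SUP", ]
  expect_equal(nrow(sup2), 4L)           # 2 per group
  expect_equal(sum(sup2$group == "CNTR"), 2L)
})

test_that("unknown index names are rejected with the known list", {
  expect_error(cohort_config(indexes = "NOPE"), "unknown index")
  expect_error(cohort_config(indexes = "NOPE"), "RMSSD")
})

test_that("lognormal-matched draws are positive with matched moments", {
  ct <- generate_cohort(cohort_config(n_per_group = 20000, indexes = "HF",
                                      distribution = "lognormal-matched",
                                      seed = 4))
  v <- ct$value[ct$group == "CNTR" & ct$condition == "SUP"]
  expect_true(all(v > 0))
  expect_lt(abs(mean(v) - 1087) / 1087, 0.05)
  expect_lt(abs(sd(v) - 1741) / 1741, 0.10)
})
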