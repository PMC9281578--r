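test_that("sample entropy equals the brute-force pair-count oracle", {
  set.seed(21)
  for (rep in 1:30) {
    n <- sample(60:220, 1)
    m <- sample(1:2, 1)
    x <- rnorm(n)
    r <- runif(1, 0.1, 0.4) * sd(x)
    expect_identical(
      unname(hrvdcan:::sampen_counts(x, m, r)),
      unname(sampen_oracle_counts(x, m, r))
    )
  }
})

test_that("sample entropy of white noise matches the analytic value", {
  # iid N(0,1), m = 1, r = 0.15: -ln P(|X - Y| <= 0.15) = 2.47
  set.seed(22)
  se <- sampen(rnorm(5000), m = 1, r = 0.15)
  expect_lt(abs(se - 2.47), 0.10)
})

test_that("predictable series have near-zero entropy; sparse data is NA", {
  x <- rep(c(1, 5, 2, 9, 3), 400)        # strictly periodic, period 5
  expect_lt(sampen(x, m = 1, r = 0.15 * sd(x)), 0.05)
  spread <- (1:100) * 1000
  expect_warning(se <- sampen(spread, m = 1, r = 1), "no template matches")
  expect_true(is.na(se))
})

test_that("MSE at scale one equals SampEn of the raw series", {
  nn <- gaussian_nn(600, 900, 40, seed = 23)
  prof <- mse_profile(nn)
  expect_equal(prof$values[1L],
               sampen(nn$intervals, m = 1, r = 0.15 * sd(nn$intervals)))
  prof_no <- suppressWarnings(mse_profile(nn, coarse_graining = "nonoverlapping"))
  expect_equal(prof_no$values[1L], prof$values[1L])
})

test_that("white-noise MSE decreases with scale under fixed tolerance", {
  nn <- gaussian_nn(3000, 900, 50, seed = 24)
  prof <- mse_profile(nn)
  expect_true(all(diff(prof$values[1:10]) < 0.02))
  expect_gt(prof$values[1L] - prof$values[10L], 0.5)
})

test_that("tau maps beat scales through the mean NN interval", {
  set.seed(30)
  x <- rnorm(400, 0, 30)
  x <- x - mean(x) + 1000                 # mean NN exactly 1000 ms
  prof <- suppressWarnings(mse_profile(nn_series(x), max_tau_s = 6))
  expect_equal(prof$tau_s, as.numeric(prof$beat_scales), tolerance = 1e-9)
})

test_that("the non-overlapping m=2 replication preset differs from default", {
  nn <- gaussian_nn(900, 900, 45, seed = 25)
  a <- mse_profile(nn)
  b <- suppressWarnings(mse_profile(nn, preset = "costa-replication"))
  common <- seq_len(min(5, length(b$values)))
  expect_false(isTRUE(all.equal(a$values[common], b$values[common])))
})

test_that("MSE enforces its preconditions and truncates short scales", {
  expect_error(mse_profile(nn_series(rep(800, 100))), "250")
  nn <- gaussian_nn(260, 900, 40, seed = 26)
  expect_warning(prof <- mse_profile(nn, coarse_graining = "nonoverlapping"),
                 "truncated")
  expect_lt(max(prof$beat_scales), 10)
})

test_that("MSE band averages follow the tau band definitions", {
  prof <- multiscale_profile(c(2.5, 5, 10), c(1.0, 2.0, 3.0), 1:3, "mse")
  mb <- mse_bands(prof)
  expect_equal(mb$mse_hf, 1.5)
  expect_equal(mb$mse_lf, 3.0)
  flat <- multiscale_profile(c(3, 6, 10, 20), rep(1.5, 4), 1:4, "mse")
  mbf <- mse_bands(flat)
  expect_equal(mbf$mse_hf, 1.5)
  expect_equal(mbf$mse_lf, 1.5)
  # a fast heart rate keeps band membership in seconds, not beats
  nn_fast <- gaussian_nn(1200, 700, 35, seed = 27)
  pf <- mse_profile(nn_fast)
  hf_scales <- pf$beat_scales[pf$tau_s >= 2.5 & pf$tau_s < 6.7]
  expect_equal(hf_scales, 4:9)
})

test_that("DFA recovers known scaling exponents", {
  set.seed(28)
  expect_lt(abs(dfa_exponent(rnorm(4096)) - 0.5), 0.1)
  expect_lt(abs(dfa_exponent(cumsum(rnorm(4096))) - 1.5), 0.1)
})

test_that("smooth oscillations give a near-2 local slope at small scales", {
  x <- 900 + 100 * sin(2 * pi * (1:2000) / 1000)
  prof <- mdfa_profile(nn_series(pmax(300, x)))
  expect_gt(prof$values[1L], 1.6)
})

test_that("alpha band averages cover the stated scale ranges", {
  prof <- multiscale_profile(c(5, 8, 11, 20, 40, 60), rep(0.9, 6), 1:6,
                             "alpha")
  ab <- alpha_bands(prof)
  expect_equal(ab$alpha_short, 0.9)
  expect_equal(ab$alpha_long, 0.9)
  narrow <- multiscale_profile(c(6, 9), c(1, 1), 1:2, "alpha")
  expect_warning(ab2 <- alpha_bands(narrow), "does not cover")
  expect_true(is.na(ab2$alpha_long))
})

test_that("white-noise alpha profile is flat near one half", {
  nn <- gaussian_nn(2000, 900, 50, seed = 29)
  ab <- alpha_bands(mdfa_profile(nn))
  expect_lt(abs(ab$alpha_short - 0.5), 0.15)
  expect_lt(abs(ab$alpha_long - 0.5), 0.15)
  expect_error(mdfa_profile(nn_series(rep(800, 300))), "500")
})
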