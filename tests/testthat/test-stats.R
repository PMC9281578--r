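test_that("AUC equals the exhaustive pair-count oracle exactly", {
  expect_equal(roc_auc(c(1, 2, 3), c(2, 3, 4), "case_low")$auc, 7 / 9)
  set.seed(51)
  for (rep in 1:30) {
    n1 <- sample(2:50, 1); n2 <- sample(2:50, 1)
    cases <- round(rnorm(n1, 10, 3), 1)     # rounding induces ties
    controls <- round(rnorm(n2, 12, 3), 1)
    dir <- sample(c("case_low", "case_high"), 1)
    expect_equal(roc_auc(cases, controls, dir)$auc,
                 auc_oracle(cases, controls, dir))
  }
})

test_that("AUC hits its boundary and null values", {
  expect_equal(roc_auc(c(1, 2, 3), c(10, 11, 12), "case_low")$auc, 1)
  x <- c(5, 6, 7, 8)
  expect_equal(roc_auc(x, x, "case_low")$auc, 0.5)
  expect_error(roc_auc(1, c(1, 2)), "at least 2")
})

test_that("group-swap symmetry holds for tie-free data", {
  set.seed(52)
  a <- rnorm(15); b <- rnorm(20, 1)
  expect_equal(roc_auc(a, b, "case_low")$auc +
                 roc_auc(b, a, "case_low")$auc, 1)
})

test_that("Hanley-McNeil and DeLong standard errors are sane", {
  set.seed(53)
  a <- rnorm(30, 10, 2); b <- rnorm(30, 12, 2)
  rh <- roc_auc(a, b, "case_low", se_method = "hanley")
  rd <- roc_auc(a, b, "case_low", se_method = "delong")
  expect_gt(rh$se, 0); expect_gt(rd$se, 0)
  expect_lt(abs(rh$se - rd$se), 0.05)
  # p-value is small for well-separated groups
  expect_lt(rh$p, 0.01)
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(54)
  cases <- rnorm(40, 10, 3); controls <- rnorm(35, 13, 3)
  mine <- roc_auc(cases, controls, "case_low")$auc
  ref <- suppressMessages(pROC::auc(
    response = c(rep(1, 40), rep(0, 35)),
    predictor = c(cases, controls), direction = ">"))
  expect_equal(mine, as.numeric(ref))
})

test_that("Youden cut-off separates and reports strict-inequality rates", {
  yc <- youden_cutoff(c(10, 20), c(30, 40), "case_low")
  expect_equal(yc$cutoff, 25)
  expect_equal(yc$sensitivity, 100)
  expect_equal(yc$specificity, 100)
  expect_warning(deg <- youden_cutoff(rep(5, 4), rep(5, 3)), "degenerate")
  expect_true(is.na(deg$cutoff))
})

test_that("Youden classification is invariant under monotone transforms", {
  set.seed(55)
  cases <- rnorm(25, 40, 10); controls <- rnorm(25, 60, 10)
  a <- youden_cutoff(cases, controls, "case_low")
  b <- youden_cutoff(exp(cases / 20), exp(controls / 20), "case_low")
  expect_equal(a$sensitivity, b$sensitivity)
  expect_equal(a$specificity, b$specificity)
  expect_equal(exp(a$cutoff / 20) > b$cutoff,
               exp(a$cutoff / 20) > b$cutoff)  # cut-offs bracket same points
  expect_equal(sum(cases < a$cutoff), sum(exp(cases / 20) < b$cutoff))
})

test_that("the normal-model rate links distributions to cut-offs", {
  expect_equal(normal_model_rate(57, 44.4, 18.0), pnorm((57 - 44.4) / 18))
  expect_equal(normal_model_rate(57, 44.4, 18.0, "case_high"),
               1 - normal_model_rate(57, 44.4, 18.0))
})

test_that("pointwise profiles flag shifted groups and spare identical ones", {
  set.seed(56)
  a <- matrix(rnorm(20 * 50), nrow = 20)
  shifted <- pointwise_group_profile(a, a + 5)
  expect_true(all(shifted$sig01))
  same <- pointwise_group_profile(a, matrix(rnorm(20 * 50), nrow = 20))
  expect_lt(mean(same$sig05), 0.15)   # near the nominal false-positive rate
  expect_error(pointwise_group_profile(a, a[, 1:10]), "grids differ")
})

test_that("small groups use the exact U distribution", {
  a <- matrix(c(1.2, 3.4, 2.2), nrow = 3)
  b <- matrix(c(9.1, 8.2, 7.3), nrow = 3)
  res <- pointwise_group_profile(a, b)
  ref <- wilcox.test(a[, 1], b[, 1], exact = TRUE)$p.value
  expect_equal(res$p, ref)
  expect_equal(res$p, 0.1, tolerance = 1e-10)  # exact 2/20 for 3 vs 3
})

test_that("BH adjustment matches hand-computed values and its bounds", {
  expect_equal(fdr_adjust(0.03), 0.03)
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(fdr_adjust(rep(0.04, 5)), rep(0.04, 5))
  set.seed(57)
  p <- runif(50)
  expect_true(all(fdr_adjust(p) >= p))
  expect_error(fdr_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("BH controls the false discovery rate under the null", {
  set.seed(58)
  any_rej <- replicate(1000, any(fdr_adjust(runif(20)) < 0.05))
  expect_lt(mean(any_rej), 0.08)   # full null: FDR = FWER <= q
})

test_that("roc_table mirrors the per-index report layout", {
  ct <- generate_cohort(cohort_config(n_per_group = 200,
                                      indexes = c("RMSSD", "SampEn"),
                                      seed = 59))
  tab <- roc_table(ct)
  expect_setequal(names(tab), c("index", "condition", "auc", "se", "p",
                                "cutoff", "sensitivity", "specificity",
                                "direction"))
  expect_equal(nrow(tab), 4L)
  rm_sup <- tab[tab$index == "RMSSD" & tab$condition == "SUP", ]
  expect_false(is.na(rm_sup$cutoff))        # significant at this n
  se_sup <- tab[tab$index == "SampEn" & tab$condition == "SUP", ]
  expect_true(is.na(se_sup$cutoff))         # null index: cut-off suppressed
})
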