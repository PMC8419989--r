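test_that("Welch t from summaries reproduces published group comparisons", {
  # EDSS: MS 2.9 +/- 1.5 (n=78) vs NMO 3.8 +/- 1.6 (n=38)
  edss <- welch_t_from_summary(2.9, 1.5, 78, 3.8, 1.6, 38)
  expect_equal(round(edss$p, 3), 0.005)
  # identical summaries
  same <- welch_t_from_summary(5, 2, 30, 5, 2, 30)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  # hand evaluation: (0,1,30) vs (1,1,30): t = -1/sqrt(2/30), df = 58
  hand <- welch_t_from_summary(0, 1, 30, 1, 1, 30)
  expect_equal(hand$t, -1 / sqrt(2 / 30), tolerance = 1e-12)
  expect_equal(hand$df, 58, tolerance = 1e-9)
  expect_equal(hand$p, 2 * pt(-abs(hand$t), 58), tolerance = 1e-12)
  expect_error(welch_t_from_summary(0, 1, 1, 1, 1, 30), "n >= 2")
})

test_that("Welch p is invariant to group order and common affine rescaling", {
  a <- welch_t_from_summary(3.1, 1.2, 40, 4.0, 1.7, 25)
  b <- welch_t_from_summary(4.0, 1.7, 25, 3.1, 1.2, 40)
  expect_equal(a$p, b$p, tolerance = 1e-12)
  scaled <- welch_t_from_summary(3.1 * 7 + 2, 1.2 * 7, 40, 4.0 * 7 + 2,
                                 1.7 * 7, 25)
  expect_equal(a$p, scaled$p, tolerance = 1e-12)
})

test_that("Welch from summaries agrees with t.test on raw data", {
  withr::with_seed(13, {
    x <- rnorm(35, 1, 2); y <- rnorm(28, 0.4, 1.4)
  })
  ours <- welch_t_from_summary(mean(x), sd(x), 35, mean(y), sd(y), 28)
  ref <- t.test(x, y)
  expect_equal(ours$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
  ours_pooled <- welch_t_from_summary(mean(x), sd(x), 35, mean(y), sd(y), 28,
                                      var_equal = TRUE)
  ref_pooled <- t.test(x, y, var.equal = TRUE)
  expect_equal(ours_pooled$p, ref_pooled$p.value, tolerance = 1e-12)
})

test_that("Yates chi-squared reproduces the published sex comparison", {
  # female/male: MS 51/27, NMO 31/7
  sex <- yates_chi2(matrix(c(51, 27, 31, 7), 2, byrow = TRUE))
  expect_equal(round(sex$p, 3), 0.114)
  # without correction the p-value is clearly smaller
  expect_lt(yates_chi2(matrix(c(51, 27, 31, 7), 2, byrow = TRUE),
                       correct = FALSE)$p, 0.08)
  # perfectly proportional table: correction clips at zero
  prop <- yates_chi2(matrix(c(20, 10, 40, 20), 2, byrow = TRUE))
  expect_equal(prop$chi2, 0)
  expect_equal(prop$p, 1)
  expect_error(yates_chi2(matrix(c(0, 0, 3, 4), 2)), "margins")
})

test_that("Yates chi-squared matches the reference implementation", {
  withr::with_seed(3, {
    for (i in 1:25) {
      m <- matrix(sample(3:60, 4), 2)
      ours <- yates_chi2(m)
      ref <- suppressWarnings(chisq.test(m, correct = TRUE))
      expect_equal(ours$chi2, unname(ref$statistic), tolerance = 1e-9)
      expect_equal(ours$p, ref$p.value, tolerance = 1e-9)
    }
  })
})

test_that("confusion metrics reproduce the reviewer worked example", {
  cm <- confusion_metrics(tp = 16, fn = 10, tn = 45, fp = 15)
  expect_equal(round(unname(cm["accuracy"]), 3), 0.709)
  expect_equal(round(unname(cm["sensitivity"]), 3), 0.615)
  expect_equal(unname(cm["specificity"]), 0.750)
  expect_equal(round(unname(cm["hard_auc"]), 3), 0.683)
  expect_equal(unname(confusion_metrics(10, 0, 10, 0)), rep(1, 4))
})

test_that("hard AUC equals the rank AUC of the implied binary predictor", {
  withr::with_seed(9, {
    for (i in 1:50) {
      cm <- sample(1:30, 4)   # tp, fn, tn, fp
      mt <- confusion_metrics(cm[1], cm[2], cm[3], cm[4])
      scores <- c(rep(1, cm[1]), rep(0, cm[2]), rep(0, cm[3]), rep(1, cm[4]))
      labels <- c(rep("P", cm[1] + cm[2]), rep("N", cm[3] + cm[4]))
      r <- rank(scores)
      n1 <- cm[1] + cm[2]; n0 <- cm[3] + cm[4]
      auc <- (sum(r[labels == "P"]) - n1 * (n1 + 1) / 2) / (n1 * n0)
      expect_equal(unname(mt["hard_auc"]), auc, tolerance = 1e-12)
    }
  })
})

test_that("class totals are reconstructed uniquely from misdiagnosis counts", {
  sol <- infer_class_totals(total = 86, correct = 61, mis_pos_as_neg = 10,
                            mis_neg_as_pos = 15, printed_sens = 0.615,
                            printed_spec = 0.750)
  expect_equal(sol$n_pos, 26)
  expect_equal(sol$n_neg, 60)
  expect_equal(sol$tp, 16)
  expect_equal(sol$tn, 45)
  expect_equal(sol$orientation, "as_given")
  expect_false(sol$ambiguous)
  # degenerate perfect case admits multiple splits
  expect_warning(amb <- infer_class_totals(4, 4, 0, 0, 1, 1), "ambiguous")
  expect_true(amb$ambiguous)
  # inconsistent printed metrics
  expect_error(infer_class_totals(86, 61, 10, 15, 0.9, 0.9), "no integer")
  expect_error(infer_class_totals(86, 60, 10, 15, 0.6, 0.7), "must equal")
})

test_that("feature-clinical correlations are symmetric with valid p-values", {
  tab <- generate_feature_cohort(synth_config(n_features = 6, seed = 18))
  feats <- grep("^H-", names(tab), value = TRUE)[1:3]
  fc <- feature_clinical_correlation(tab, feats)
  k <- length(feats) + 4
  expect_equal(dim(fc$r), c(k, k))
  expect_equal(fc$r, t(fc$r))
  expect_equal(unname(diag(fc$r)), rep(1, k))
  expect_true(all(fc$p >= 0 & fc$p <= 1))
  # a feature equal to a covariate correlates perfectly
  tab$`H-T2-original-firstorder-Mean` <- tab$age
  fc2 <- feature_clinical_correlation(tab, "H-T2-original-firstorder-Mean")
  expect_equal(fc2$r["H-T2-original-firstorder-Mean", "age"], 1)
  expect_lt(fc2$p["H-T2-original-firstorder-Mean", "age"], 1e-10)
  expect_true(fc2$significant["H-T2-original-firstorder-Mean", "age"])
  # 5-point hand-computable pair against the covariance formula
  x <- c(1, 2, 3, 4, 5); y <- c(2, 1, 4, 3, 6)
  r_hand <- sum((x - 3) * (y - mean(y))) /
    sqrt(sum((x - 3)^2) * sum((y - mean(y))^2))
  small <- data.frame(subject_id = as.character(1:5), diagnosis = "MS",
                      scanner = "3T", age = y, sex = c(0, 1, 0, 1, 0),
                      edss = c(1, 2, 1.5, 3, 2.5), duration = 10:14,
                      `H-T2-original-firstorder-Mean` = x, check.names = FALSE)
  fc3 <- feature_clinical_correlation(small, "H-T2-original-firstorder-Mean",
                                      covariates = "age")
  expect_equal(fc3$r[1, 2], r_hand, tolerance = 1e-12)
  expect_error(feature_clinical_correlation(small[1:2, ],
                                            "H-T2-original-firstorder-Mean"),
               "3 subjects")
})

test_that("independent columns rarely show strong correlation", {
  withr::with_seed(44, {
    tab <- generate_feature_cohort(synth_config(
      n_features = 10, n_discriminative = 0, n_scanner_shifted = 0,
      block_correlation = 0, seed = 44))
  })
  feats <- grep("^H-", names(tab), value = TRUE)
  fc <- feature_clinical_correlation(tab, feats, covariates = "age")
  off <- abs(fc$r[feats, "age"])
  expect_gt(mean(off < 0.25), 0.9)
})
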