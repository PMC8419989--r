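test_that("the registry enumerates 1118 uniquely named features per sequence", {
  reg <- feature_registry("T2")
  expect_equal(nrow(reg), 1118)
  expect_false(anyDuplicated(reg$name) > 0)
  expect_identical(reg$id, seq_len(1118))
  # family subtotals: 18 first-order + 68 texture per image, x 13 images
  expect_equal(sum(reg$filter == "original"), 86)
  expect_equal(sum(startsWith(reg$filter, "log")), 344)
  expect_equal(sum(startsWith(reg$filter, "wavelet")), 688)
  expect_equal(sum(reg$family == "firstorder" & reg$filter == "original"), 18)
  expect_equal(sum(reg$family != "firstorder" & reg$filter == "original"), 68)
  expect_true("H-T2-waveletHHL-glcm-Idn" %in% reg$name)
  expect_true("H-MPR-log3-firstorder-Median" %in% feature_registry("MPR")$name)
})

test_that("discretization follows the min-referenced fixed-bin-width rule", {
  expect_equal(discretize(c(5, 5, 5), 10)$levels, c(1L, 1L, 1L))
  expect_equal(discretize(c(5, 5, 5), 10)$ng, 1L)
  dz <- discretize(c(0, 24.9, 25, 50), 25)
  expect_equal(dz$levels, c(1L, 1L, 2L, 3L))
  expect_equal(dz$ng, 3L)
  expect_error(discretize(c(1, 2), 0), "bin_width")
  withr::with_seed(4, v <- runif(200, 0, 120))
  dz <- discretize(v, 25)
  expect_equal(dz$levels, vapply(v, function(x)
    as.integer(floor((x - min(v)) / 25)) + 1L, 1L))
})

test_that("the LoG filter annihilates constants and linear ramps", {
  cv <- array(7, c(9, 9, 9))
  expect_lt(max(abs(log_filter(cv, 2))), 1e-12)
  ramp <- array(rep(seq_len(15), times = 15 * 15), c(15, 15, 15))
  resp <- log_filter(ramp, 1)
  interior <- resp[6:10, 6:10, 6:10]       # away from the replicated boundary
  expect_lt(max(abs(interior)), 1e-10)
  expect_error(log_filter(cv, -1), "sigma")
})

test_that("the LoG impulse response matches the analytic kernel", {
  d <- c(25, 25, 25)
  imp <- array(0, d); imp[13, 13, 13] <- 1
  resp <- log_filter(imp, 1.5)
  x <- (-12:12)
  g <- function(x, s) exp(-x^2 / (2 * s^2)) / (s * sqrt(2 * pi))
  g2 <- function(x, s) (x^2 - s^2) / s^4 * g(x, s)
  analytic <- outer(outer(g2(x, 1.5), g(x, 1.5)), g(x, 1.5)) +
    outer(outer(g(x, 1.5), g2(x, 1.5)), g(x, 1.5)) +
    outer(outer(g(x, 1.5), g(x, 1.5)), g2(x, 1.5))
  expect_lt(max(abs(resp - analytic)), 1e-6)
})

test_that("wavelet subbands are labelled, energy preserving, and tap-exact", {
  cv <- array(3, c(4, 4, 4))
  wb <- wavelet_subbands(cv)
  expect_named(wb, c("LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH"))
  expect_true(all(abs(wb$LLL - 3 * sqrt(2)^3) < 1e-12))
  for (lab in names(wb)[-1]) expect_lt(max(abs(wb[[lab]])), 1e-12)
  # Parseval for the orthonormal kernel on even dimensions
  withr::with_seed(8, x <- array(rnorm(6 * 4 * 8), c(6, 4, 8)))
  wb <- wavelet_subbands(x)
  expect_equal(sum(vapply(wb, function(a) sum(a^2), 0)), sum(x^2),
               tolerance = 1e-10)
  # impulse: subband coefficients are tensor products of the 1-D taps
  imp <- array(0, c(4, 4, 4)); imp[1, 1, 1] <- 1
  wb <- wavelet_subbands(imp)
  h <- 1 / sqrt(2)
  for (lab in names(wb)) {
    expect_equal(wb[[lab]][1, 1, 1], h^3, tolerance = 1e-12)
    expect_equal(sum(wb[[lab]]^2), h^6, tolerance = 1e-12)
  }
  expect_error(wavelet_subbands(array(1, c(1, 4, 4))), "length >= 2")
})

test_that("first-order statistics match direct formulas", {
  fo <- first_order_features(c(2, 4, 4, 5))
  expect_equal(unname(fo["Median"]), 4)
  expect_equal(unname(fo["Mean"]), 3.75)
  expect_equal(unname(fo["Range"]), 3)
  # constant input: degenerate moments are 0 by convention
  fc <- first_order_features(rep(3, 10))
  expect_equal(unname(fc[c("Mean", "Median", "Minimum", "Maximum")]),
               rep(3, 4))
  expect_equal(unname(fc[c("Variance", "Skewness", "Kurtosis")]), rep(0, 3))
  expect_equal(unname(fc["Uniformity"]), 1)
  # random sample against an independent direct-formula oracle
  withr::with_seed(21, v <- runif(50, 0, 90))
  fo <- first_order_features(v, bin_width = 25)
  n <- length(v)
  q <- quantile(v, c(0.1, 0.25, 0.5, 0.75, 0.9), type = 7)
  rob <- v[v >= q[[1]] & v <= q[[5]]]
  lev <- floor((v - min(v)) / 25) + 1
  pr <- as.numeric(table(lev)) / n
  oracle <- c(Energy = sum(v^2), Entropy = -sum(pr * log2(pr)),
              Minimum = min(v), Percentile10 = q[[1]], Percentile90 = q[[5]],
              Maximum = max(v), Mean = mean(v), Median = q[[3]],
              InterquartileRange = q[[4]] - q[[2]], Range = max(v) - min(v),
              MeanAbsoluteDeviation = mean(abs(v - mean(v))),
              RobustMeanAbsoluteDeviation = mean(abs(rob - mean(rob))),
              RootMeanSquared = sqrt(mean(v^2)),
              StandardDeviation = sqrt(mean((v - mean(v))^2)),
              Variance = mean((v - mean(v))^2),
              Skewness = mean((v - mean(v))^3) / mean((v - mean(v))^2)^1.5,
              Kurtosis = mean((v - mean(v))^4) / mean((v - mean(v))^2)^2,
              Uniformity = sum(pr^2))
  expect_equal(fo, oracle, tolerance = 1e-9)
  expect_error(first_order_features(numeric(0)), "empty")
})

test_that("GLCM matches hand-enumerated and degenerate cases", {
  # 1-D strip with levels 1,1,2,2 at distance 1, symmetric:
  # p = {(1,1): 1/3, (1,2): 1/6, (2,1): 1/6, (2,2): 1/3}
  v <- array(c(0, 0, 30, 30), c(4, 1, 1)); m <- array(1, c(4, 1, 1))
  g <- glcm_features(v, m, 25)
  expect_equal(unname(g["Autocorrelation"]), 7 / 3, tolerance = 1e-12)
  expect_equal(unname(g["JE"]),
               -(2 * (1 / 3) * log2(1 / 3) + 2 * (1 / 6) * log2(1 / 6)),
               tolerance = 1e-12)
  # constant VOI: single-cell matrix with p = 1
  vc <- array(5, c(3, 3, 2)); mc <- array(1, c(3, 3, 2))
  gc <- glcm_features(vc, mc, 25)
  expect_equal(unname(gc[c("JE", "Idn", "Idmn", "Autocorrelation")]),
               c(0, 1, 1, 1))
  # isolated voxels: no valid pair in any direction -> zeros, flagged
  vs <- array(0, c(5, 1, 1)); ms <- array(c(1, 0, 0, 0, 1), c(5, 1, 1))
  gs <- glcm_features(vs, ms, 25)
  expect_true(attr(gs, "undefined"))
  expect_true(all(gs == 0))
})

test_that("GLSZM zone labelling matches hand cases", {
  v <- array(c(0, 0, 30), c(3, 1, 1)); m <- array(1, c(3, 1, 1))
  s <- glszm_features(v, m, 25)
  expect_equal(unname(s["GLNU"]), 1)      # (1^2 + 1^2) / 2 zones
  expect_equal(unname(s["ZP"]), 2 / 3)
  vc <- array(4, c(3, 3, 1)); mc <- array(1, c(3, 3, 1))
  expect_equal(unname(glszm_features(vc, mc, 25)["GLNU"]), 1) # single zone
})

test_that("texture families match brute-force oracles on random small VOIs", {
  for (s in 101:110) expect_texture_oracle_match(random_voi(s))
})

test_that("texture features are invariant to constant intensity offsets", {
  voi <- random_voi(42)
  for (fn in list(glcm_features, glrlm_features, glszm_features, gldm_features)) {
    a <- fn(voi$vol, voi$mask, 25)
    b <- fn(voi$vol + 1000, voi$mask, 25)
    expect_equal(a, b, tolerance = 1e-12)
  }
})

test_that("extract_all produces the full named record deterministically", {
  cfg <- synth_config(n_ms_3t = 1, n_nmo_3t = 0, n_ms_15t = 0, n_nmo_15t = 0,
                      volume_dim = c(16, 16, 16), seed = 9)
  pair <- generate_volume_cohort(cfg)[[1]]
  rec <- extract_all(pair)
  expect_equal(sum(startsWith(names(rec), "H-T2-")), 1118)
  expect_equal(sum(startsWith(names(rec), "H-MPR-")), 1118)
  expect_equal(sum(!startsWith(names(rec), "H-")), 4)
  expect_false(anyNA(rec))
  expect_identical(rec, extract_all(pair))
  # family subtotals within one sequence
  t2 <- grep("^H-T2-", names(rec), value = TRUE)
  expect_equal(sum(grepl("-original-", t2)), 86)
  expect_equal(sum(grepl("-log[0-9]", t2)), 344)
  expect_equal(sum(grepl("-wavelet", t2)), 688)
})

test_that("planted image-level class texture is detected through the pipeline", {
  # two classes differ only in within-lesion texture autocorrelation length;
  # a rank-sum screen on extracted T2 texture features must find it
  cfg <- synth_config(n_ms_3t = 10, n_nmo_3t = 10, n_ms_15t = 10,
                      n_nmo_15t = 10, volume_dim = c(16, 16, 16),
                      lesion_count_range = c(1, 2), seed = 27)
  tab <- extract_cohort(generate_volume_cohort(cfg))
  texture <- grep("^H-T2-original-(glcm|glrlm|glszm|gldm)-", names(tab),
                  value = TRUE)
  pvals <- vapply(texture, function(f)
    rank_sum_test(tab[[f]][tab$diagnosis == "NMO"],
                  tab[[f]][tab$diagnosis == "MS"])$p, 0)
  expect_lt(min(pvals), 1e-4)
})

test_that("standardization is exact, invertible, and flags constants", {
  cfg <- synth_config(n_ms_3t = 10, n_nmo_3t = 10, n_ms_15t = 10,
                      n_nmo_15t = 10, n_features = 12, seed = 2)
  tab <- generate_feature_cohort(cfg)
  feats <- grep("^H-", names(tab), value = TRUE)
  st <- standardize(tab, tab)
  for (f in feats) {
    expect_lt(abs(mean(st[[f]])), 1e-9)
    expect_lt(abs(sd(st[[f]]) - 1), 1e-9)
  }
  # constant feature column maps to zero and is flagged
  tab2 <- tab
  tab2[[feats[1]]] <- 3
  st2 <- standardize(tab2, tab2)
  expect_true(all(st2[[feats[1]]] == 0))
  expect_true(feats[1] %in% attr(st2, "constant_columns"))
  # round trip: standardize test against train, invert with train stats
  sp <- split_train_test(tab, 25, seed = 1)
  stest <- standardize(sp$test, sp$train)
  back <- unstandardize(stest)
  for (f in feats)
    expect_equal(back[[f]], sp$test[[f]], tolerance = 1e-9)
  expect_error(standardize(tab[, 1:8], tab[, 1:7]), "missing")
})
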