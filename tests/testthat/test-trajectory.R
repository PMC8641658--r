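test_that("trapezoid AUC is exact on constant and linear series", {
  # constant e over PODs 1..7: ln = 1, span 6
  expect_equal(trapezoid_auc(1:7, rep(exp(1), 7), c(1, 7), "ln"), 6.0)
  # ln-linear 2 + 0.5*pod: trapezoid equals the exact integral over [1,7]
  v <- exp(2 + 0.5 * (1:7))
  exact <- integrate(function(t) 2 + 0.5 * t, 1, 7)$value
  expect_equal(trapezoid_auc(1:7, v, c(1, 7), "ln"), exact,
               tolerance = 1e-12)
  # interior gaps bridge linearly: PODs {1,3,7}, ln-values all 1
  expect_equal(trapezoid_auc(c(1, 3, 7), rep(exp(1), 3), c(1, 7), "ln"), 6.0)
})

test_that("missing window endpoints rescale by full span / observed span", {
  # PODs 2..7 constant e: observed-span area 5, rescaled to 6
  expect_equal(trapezoid_auc(2:7, rep(exp(1), 6), c(1, 7), "ln"), 6.0)
  # normalized switch divides by window span
  expect_equal(trapezoid_auc(1:7, rep(exp(3), 7), c(1, 7), "ln",
                             normalized = TRUE), 3.0)
})

test_that("trapezoid matches a dense Riemann oracle on linear inputs", {
  set.seed(11)
  for (k in 1:20) {
    a <- runif(1, -1, 3); b <- runif(1, -0.4, 0.4)
    pods <- sort(sample(1:10, sample(3:10, 1)))
    w <- c(1, 10)
    t <- seq(max(min(pods), w[1]), min(max(pods), w[2]), length.out = 20001)
    riemann <- sum((a + b * t[-1] + a + b * t[-length(t)]) / 2 * diff(t)) *
      (w[2] - w[1]) / (max(pods) - min(pods))
    expect_equal(trapezoid_auc(pods, exp(a + b * pods), w, "ln"), riemann,
                 tolerance = 1e-9)
  }
})

test_that("AUC and slope obey log-scaling laws", {
  set.seed(7)
  for (k in 1:25) {
    pods <- sort(sample(1:10, sample(3:10, 1)))
    v <- exp(rnorm(length(pods), 1, 0.8))
    kpos <- exp(runif(1, -2, 2))
    w <- c(1, 10)
    a1 <- trapezoid_auc(pods, v, w, "ln")
    a2 <- trapezoid_auc(pods, kpos * v, w, "ln")
    expect_equal(a2, a1 + (w[2] - w[1]) * log(kpos), tolerance = 1e-10)
    expect_equal(ols_slope(pods, kpos * v, w, "ln"),
                 ols_slope(pods, v, w, "ln"), tolerance = 1e-10)
  }
})

test_that("OLS slope recovers linear trends and hand-computed cases", {
  expect_equal(ols_slope(1:7, exp(3 - 0.2 * (1:7)), c(1, 7), "ln"), -0.2)
  expect_equal(ols_slope(1:7, rep(5, 7), c(1, 7), "ln"), 0)
  # PODs {1,2,7}, ln-values {0,1,2}: closed-form OLS slope 9/31
  expect_equal(ols_slope(c(1, 2, 7), exp(c(0, 1, 2)), c(1, 7), "ln"),
               9 / 31, tolerance = 1e-12)
  expect_true(is.na(ols_slope(c(3, 3), c(1, 2), c(1, 7), "identity")))
  expect_true(is.na(trapezoid_auc(4, 2, c(1, 7), "identity")))
  expect_error(ols_slope(1:3, c(1, -1, 2), c(1, 7), "ln"), "non-positive")
})

test_that("extract_features applies the coverage rule per model", {
  full <- normal_labs(1:10)
  for (m in c("lgraft7", "lgraft10", "ease", "meaf", "ead"))
    expect_true(extract_features(full, m)$sufficient)

  # POD-3 TBIL missing: MEAF insufficient, L-GrAFT7 unaffected
  no3 <- full[!(full$analyte == "TBIL" & full$pod == 3), ]
  expect_false(extract_features(no3, "meaf")$sufficient)
  expect_match(extract_features(no3, "meaf")$missing, "TBIL", all = FALSE)
  expect_true(extract_features(no3, "lgraft7")$sufficient)

  # PODs 1-2 only: nothing but the MEAF max terms is computable
  early <- normal_labs(1:2)
  for (m in c("lgraft7", "lgraft10", "ease", "ead"))
    expect_false(extract_features(early, m)$sufficient)
  fm <- extract_features(early, "meaf")
  expect_false(fm$sufficient)
  expect_false(anyNA(fm$features[c("alt_max_3pod", "inr_max_3pod")]))

  # EASE needs POD 10 (the only subset day in the window tail)
  no10 <- normal_labs(1:9)
  expect_false(extract_features(no10, "ease")$sufficient)
  expect_true(extract_features(no10, "lgraft10")$sufficient)
})

test_that("feature values route the documented windows and subsets", {
  # AST decaying log-linearly; subset vs full-window AUC differ accordingly
  labs <- make_labs(list(AST = exp(8 - 0.3 * (1:10)), ALT = 100,
                         TBIL = 2, INR = 1.2, PLT = 100), 1:10)
  f7 <- extract_features(labs, "lgraft7")$features
  f10 <- extract_features(labs, "lgraft10")$features
  expect_equal(unname(f7[["slope_ln_ast"]]), -0.3, tolerance = 1e-10)
  expect_equal(unname(f10[["slope7_ln_ast"]]), -0.3, tolerance = 1e-10)
  # trapezoid exact for linear: integral of (8-0.3t) over [1,7] and [1,10]
  expect_equal(unname(f7[["auc_ln_ast"]]), 6 * 8 - 0.3 * (49 - 1) / 2,
               tolerance = 1e-10)
  expect_equal(unname(f10[["auc_ln_ast"]]), 9 * 8 - 0.3 * (100 - 1) / 2,
               tolerance = 1e-10)
  # L-GrAFT7 INR feature is the raw-scale AUC
  expect_equal(unname(f7[["auc_inr"]]), 6 * 1.2, tolerance = 1e-10)
  expect_equal(unname(f10[["max_inr"]]), 1.2)
  # MEAF bilirubin comes from POD 3 exactly
  fm <- extract_features(labs, "meaf")$features
  expect_equal(unname(fm[["bilirubin_pod3"]]), 2)
})
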