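# Independent term-by-term oracles, coded from the printed formulas and
# kept separate from the implementation under R/.

oracle_meaf <- function(alt, inr, bili) {
  3.29 / (1 + exp(-1.9132 * (log(alt) - 6.1723))) +
  3.29 / (1 + exp(-6.8204 * (log(inr) - 0.6658))) +
  3.40 / (1 + exp(-1.8005 * (log(bili) - 1.0607)))
}

oracle_lgraft7 <- function(a, sa, ai, b, sb, p) {
  terms <- c(6.9647, -0.5799 * a, 0.00844 * a^2, 5.25347 * sa,
             4.65046 * sa^2, 1.14098 * log(ai), -0.03475 * b,
             0.00562 * b^2, 4.31135 * sb, 5.84724 * sb^2, -0.05115 * p)
  sum(terms)
}

oracle_lgraft10 <- function(a, s7a, mi, b, sb, p, sp) {
  sum(c(9.77, -0.42926 * a, 0.00462 * a^2, 4.60719 * s7a, 4.4129 * s7a^2,
        0.88974 * log(mi), -0.04852 * b, 0.00363 * b^2, 5.33627 * sb,
        -0.04621 * p, -5.24897 * sp, 13.08633 * sp^2))
}

oracle_ease <- function(meld, rbc, thromb, a, p, sp, sb, center) {
  sum(c(-0.602, 0.044 * meld, 0.065 * rbc, 2.567 * thromb,
        0.000534 * a^2, -0.093 * p, -7.766 * sp, 0.795 * sb,
        -0.402 * center))
}

test_that("EAD boundary semantics match the printed criteria", {
  pos1 <- make_labs(list(AST = 150, ALT = 150, TBIL = c(rep(2, 6), 10),
                         INR = 1.2, PLT = 100), 1:7)
  r <- classify_ead(pos1)
  expect_true(r$ead)
  expect_equal(r$criteria,
               c(bilirubin = TRUE, inr = FALSE, transaminase = FALSE))

  # all three just below/at their negative side: 9.9, 1.59, ALT exactly 2000
  neg <- make_labs(list(AST = 150, ALT = c(2000, rep(150, 6)),
                        TBIL = c(rep(2, 6), 9.9),
                        INR = c(rep(1.1, 6), 1.59), PLT = 100), 1:7)
  expect_false(classify_ead(neg)$ead)

  expect_false(classify_ead(normal_labs(1:7))$ead)
  expect_false(any(classify_ead(normal_labs(1:7))$criteria))

  # missing POD-7 bilirubin: insufficient, not guessed
  r2 <- classify_ead(normal_labs(1:6))
  expect_true(is.na(r2$ead))
  expect_false(r2$sufficient)
})

test_that("classify_ead is monotone in the lab values", {
  set.seed(33)
  for (k in 1:50) {
    tb <- runif(1, 1, 15); inr <- runif(1, 0.9, 2.2)
    am <- runif(1, 300, 3000)
    labs <- make_labs(list(AST = am, ALT = am * 0.9, TBIL = tb, INR = inr,
                           PLT = 100), 1:7)
    base <- classify_ead(labs)$ead
    up <- labs; up$value <- up$value * runif(nrow(up), 1, 1.5)
    if (base) expect_true(classify_ead(up)$ead)
  }
})

test_that("MEAF midpoints, hand oracle and bounds", {
  m <- meaf_score(exp(6.1723), exp(0.6658), exp(1.0607))
  expect_equal(unname(m$components), c(1.645, 1.645, 1.70),
               tolerance = 1e-12)
  expect_equal(m$score, 4.99, tolerance = 1e-12)
  expect_equal(m$group, 2L)

  m2 <- meaf_score(1000, 1.2, 1.0)
  expect_equal(m2$score, oracle_meaf(1000, 1.2, 1.0), tolerance = 1e-12)

  big <- meaf_score(1e12, 1e12, 1e12)
  expect_lt(big$score, 9.98 + 1e-9)
  expect_equal(big$score, 9.98, tolerance = 1e-6)
  expect_equal(big$group, 5L)
  expect_error(meaf_score(-1, 1, 1), "positive")

  # components strictly increasing and amplitude-bounded
  set.seed(5)
  x <- sort(exp(runif(40, -3, 10)))
  comp <- vapply(x, function(v) meaf_score(v, 1, 1)$components[["alt"]],
                 numeric(1))
  expect_true(all(diff(comp) > 0))
  expect_true(all(comp > 0 & comp < 3.29))
})

test_that("L-GrAFT predictors match the term-by-term oracles", {
  f0 <- c(auc_ln_ast = 0, slope_ln_ast = 0, auc_inr = 1, auc_ln_tbil = 0,
          slope_ln_tbil = 0, auc_ln_plt = 0)
  expect_identical(lgraft7_score(f0), 6.9647)
  rg <- assign_risk_group(6.9647, "lgraft7")
  expect_equal(rg$group, 7L)
  expect_true(rg$high)

  f <- c(auc_ln_ast = 10, slope_ln_ast = -0.1, auc_inr = 7,
         auc_ln_tbil = 5, slope_ln_tbil = -0.05, auc_ln_plt = 30)
  expect_equal(lgraft7_score(f), oracle_lgraft7(10, -0.1, 7, 5, -0.05, 30),
               tolerance = 1e-12)
  expect_equal(round(lgraft7_score(f), 2), 1.98)

  # negating a slope changes only its linear term (quadratic is even)
  s <- 0.13
  fp <- f; fp[["slope_ln_ast"]] <- s
  fm <- f; fm[["slope_ln_ast"]] <- -s
  expect_equal(lgraft7_score(fp) - lgraft7_score(fm), 2 * 5.25347 * s,
               tolerance = 1e-12)
  expect_error(lgraft7_score(replace(f, "auc_inr", 0)), "positive")

  g0 <- c(auc_ln_ast = 0, slope7_ln_ast = 0, max_inr = 1, auc_ln_tbil = 0,
          slope_ln_tbil = 0, auc_ln_plt = 0, slope_ln_plt = 0)
  expect_identical(lgraft10_score(g0), 9.77)
  g <- c(auc_ln_ast = 45, slope7_ln_ast = -0.2, max_inr = 1.8,
         auc_ln_tbil = 12, slope_ln_tbil = 0.08, auc_ln_plt = 38,
         slope_ln_plt = 0.05)
  expect_equal(lgraft10_score(g),
               oracle_lgraft10(45, -0.2, 1.8, 12, 0.08, 38, 0.05),
               tolerance = 1e-12)
  expect_equal(assign_risk_group(-3.24, "lgraft10")$group, 1L)
})

test_that("EASE intercept and indicator coefficients are exact", {
  f0 <- c(auc_ln_ast = 0, auc_ln_plt = 0, slope_ln_plt = 0,
          slope_ln_tbil = 0)
  e <- ease_score(0, 0, FALSE, FALSE, f0)
  expect_identical(e$score, -0.602)
  et <- ease_score(0, 0, TRUE, FALSE, f0)
  expect_equal(et$score - e$score, 2.567, tolerance = 1e-12)
  ec <- ease_score(0, 0, FALSE, TRUE, f0)
  expect_equal(ec$score - e$score, -0.402, tolerance = 1e-12)
  f <- c(auc_ln_ast = 38, auc_ln_plt = 30, slope_ln_plt = 0.04,
         slope_ln_tbil = -0.1)
  expect_equal(ease_score(22, 6, TRUE, TRUE, f)$score,
               oracle_ease(22, 6, 1, 38, 30, 0.04, -0.1, 1),
               tolerance = 1e-12)
})

test_that("risk-group bins follow the printed closure conventions", {
  expect_equal(assign_risk_group(-1.5, "lgraft7")$group, 4L)
  expect_true(assign_risk_group(-1.5, "lgraft7")$high)
  expect_false(assign_risk_group(-1.5 - 1e-9, "lgraft7")$high)
  expect_equal(assign_risk_group(2.0, "meaf")$group, 1L)
  expect_equal(assign_risk_group(2.0 + 1e-12, "meaf")$group, 2L)
  expect_equal(assign_risk_group(-1.0, "ease")$group, 3L)
  # the printed EASE gap between -1.26 and -1.25 closes under 2-dp rounding
  expect_equal(assign_risk_group(-1.2551, "ease")$group, 2L)
  expect_equal(assign_risk_group(-1.2549, "ease")$group, 3L)
  # out-of-range scores clamp to terminal bins with a warning
  expect_warning(g <- assign_risk_group(8.2, "lgraft7")$group, "clamped")
  expect_equal(g, 7L)
  expect_warning(g2 <- assign_risk_group(6.3, "ease")$group, "clamped")
  expect_equal(g2, 5L)

  # binning is total over the representable score line
  set.seed(9)
  ngroups <- c(meaf = 5L, lgraft7 = 7L, lgraft10 = 5L, ease = 5L)
  for (m in names(ngroups)) {
    lim <- switch(m, meaf = c(1e-6, 10), lgraft7 = c(-8, 7.49),
                  lgraft10 = c(-8, 8), ease = c(-6, 5))
    g <- vapply(runif(200, lim[1], lim[2]),
                function(x) assign_risk_group(x, m)$group, integer(1))
    expect_true(all(g >= 1L & g <= ngroups[[m]]))
  }
})

test_that("score_panel computes what the labs support and nothing more", {
  clin <- make_clinical()
  full <- score_panel(normal_labs(1:10), clin)
  expect_true(all(unlist(full[grep("sufficient", names(full))])))
  expect_false(anyNA(full[c("meaf", "lgraft7", "lgraft10", "ease")]))

  week1 <- score_panel(normal_labs(1:7), clin)
  expect_true(week1$lgraft7_sufficient)
  expect_true(week1$meaf_sufficient)
  expect_true(week1$ead_sufficient)
  expect_false(week1$lgraft10_sufficient)
  expect_false(week1$ease_sufficient)
  expect_true(is.na(week1$lgraft10) && is.na(week1$ease))

  empty <- score_panel(normal_labs(integer(0)), clin)
  expect_false(any(unlist(empty[grep("sufficient", names(empty))])))
})
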