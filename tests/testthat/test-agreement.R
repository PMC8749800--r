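test_that("the KS gate accepts normal and rejects uniform samples", {
  set.seed(11)
  expect_true(normality_test(rnorm(1000))$is_normal)
  expect_false(normality_test(runif(1000))$is_normal)
  deg <- normality_test(rep(1.5, 3))
  expect_false(deg$is_normal)
  expect_true(is.na(deg$p))
})

test_that("fixed-bias testing detects a shift and respects the null", {
  expect_equal(fixed_bias_test(rep(0, 50), normal = FALSE), 1)
  set.seed(3)
  d <- rnorm(342, 0.5, 1)
  expect_lt(fixed_bias_test(d, normal = TRUE), 1e-3)
  expect_lt(fixed_bias_test(round(d, 1), normal = FALSE), 1e-3)
  # under a symmetric null the non-parametric branch keeps its size
  set.seed(13)
  rejections <- sum(replicate(200, {
    fixed_bias_test(sample(c(-1, 1), 342, TRUE) * rexp(342), normal = FALSE) < 0.05
  }))
  expect_lte(rejections, 20)  # >= 90% non-rejections
})

test_that("the Pratt signed-rank agrees with the classic test when no zeros or ties", {
  set.seed(21)
  for (i in 1:10) {
    d <- rnorm(80, 0.2)
    p_ref <- stats::wilcox.test(d, mu = 0, exact = FALSE, correct = FALSE)$p.value
    expect_equal(fixed_bias_test(d, normal = FALSE), p_ref, tolerance = 1e-8)
  }
})

test_that("proportional-bias testing reacts to a trend and not to noise", {
  set.seed(31)
  A <- rnorm(500, 10, 2)
  res0 <- proportional_bias_test(rnorm(500), A, normal_both = TRUE)
  expect_gt(res0$p, 0.05)
  res1 <- proportional_bias_test(0.3 * A + rnorm(500, 0, 0.5), A, TRUE)
  expect_lt(res1$p, 0.05)
  expect_gt(res1$r, 0.5)
  expect_equal(proportional_bias_test(rep(2, 10), 1:10, FALSE),
               list(r = 0, p = 1))
})

test_that("classic limits of agreement match their closed forms", {
  set.seed(5)
  D <- rnorm(1e5)
  lim <- loa_classic(D, normal = TRUE)
  expect_equal(unname(lim), c(-1.96, 1.96), tolerance = 0.02)
  expect_equal(unname(loa_classic(rep(3, 10), normal = FALSE)), c(3, 3))
  U <- runif(1e5)
  expect_equal(unname(loa_classic(U, normal = FALSE)), c(0.025, 0.975),
               tolerance = 0.005)
})

test_that("parametric corrected limits reduce to 1.96 sigma for normal residuals", {
  set.seed(41)
  A <- rnorm(2e4, 10, 2)
  D <- 2 + rnorm(2e4, 0, 1.5)
  res <- loa_parametric_corrected(D, A)
  expect_equal(unname(res$pa_line["intercept"]), 2, tolerance = 0.1)
  expect_equal(unname(res$pa_line["slope"]), 0, tolerance = 0.02)
  expect_equal(res$half_width, 1.96 * 1.5, tolerance = 0.03)
  # least-squares oracle: closed-form slope and intercept
  b1 <- cov(A, D) / var(A); b0 <- mean(D) - b1 * mean(A)
  expect_equal(unname(res$pa_line), c(b0, b1), tolerance = 1e-10)
  # noise-free linear disagreement: limits collapse onto the PA line
  Dl <- 0.5 + 0.2 * A
  resl <- loa_parametric_corrected(Dl, A)
  expect_equal(resl$half_width, 0, tolerance = 1e-10)
  expect_equal(resl$lower, resl$upper, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("quantile limit lines match the exhaustive pinball-grid oracle", {
  set.seed(51)
  x <- runif(50, 0, 10)
  y <- 1 + 0.5 * x + rnorm(50)
  fit <- loa_quantile_corrected(y, x)
  for (tau in c(0.5)) {
    grid <- oracle_quantile_line(x, y, tau,
                                 c0_grid = seq(-1, 3, by = 0.02),
                                 c1_grid = seq(0, 1, by = 0.01))
    own_loss <- oracle_pinball(x, y, fit$pa_line["intercept"],
                               fit$pa_line["slope"], tau)
    # the fitted line must be at least as good as the best grid point
    expect_lte(own_loss, grid$loss + 1e-8)
    expect_equal(unname(fit$pa_line), grid$coef, tolerance = 0.05)
  }
  # constant differences: all three lines equal the constant
  cfit <- suppressWarnings(loa_quantile_corrected(rep(2, 30), runif(30)))
  for (ln in cfit) {
    expect_equal(unname(ln["intercept"]), 2, tolerance = 1e-6)
    expect_equal(unname(ln["slope"]), 0, tolerance = 1e-6)
  }
})

test_that("uniform noise around a slope gives the known quantile lines", {
  set.seed(61)
  A <- runif(2e4, 0, 10)
  D <- A + runif(2e4, -1, 1)
  res <- loa_quantile_corrected(D, A)
  expect_equal(unname(res$upper["intercept"]), 0.95, tolerance = 0.06)
  expect_equal(unname(res$lower["intercept"]), -0.95, tolerance = 0.06)
  expect_equal(unname(res$upper["slope"]), 1, tolerance = 0.02)
  expect_equal(unname(res$lower["slope"]), 1, tolerance = 0.02)
})

test_that("ICC matches its variance-component value and the ANOVA oracle", {
  expect_equal(icc(1:30, 1:30)$icc, 1)
  expect_equal(icc(1:30, 1:30, "2,k")$icc, 1)
  set.seed(9)
  mu <- rnorm(500, 50, 3)               # between-target variance 9 sigma^2
  x1 <- mu + rnorm(500); x2 <- mu + rnorm(500)
  expect_equal(icc(x1, x2)$icc, 0.9, tolerance = 0.03)
  # independent raters carry no agreement
  expect_equal(icc(rnorm(500), rnorm(500))$icc, 0, tolerance = 0.1)
  # oracle: the same mean squares out of stats::aov
  n <- 40
  m <- cbind(rnorm(n, 10, 2), rnorm(n, 10, 2) + rnorm(n))
  df <- data.frame(y = c(m), subj = factor(rep(1:n, 2)),
                   rater = factor(rep(1:2, each = n)))
  ms <- summary(stats::aov(y ~ subj + rater, df))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  expect_equal(icc(m[, 1], m[, 2])$icc,
               (msr - mse) / (msr + mse + 2 * (msc - mse) / n),
               tolerance = 1e-10)
  expect_equal(icc(m[, 1], m[, 2], "2,k")$icc,
               (msr - mse) / (msr + (msc - mse) / n), tolerance = 1e-10)
})

test_that("the average-measure ICC dominates the single-measure ICC", {
  set.seed(71)
  for (i in 1:20) {
    mu <- rnorm(60, 0, runif(1, 0.5, 4))
    x1 <- mu + rnorm(60); x2 <- mu + rnorm(60)
    expect_gte(icc(x1, x2, "2,k")$icc, icc(x1, x2, "2,1")$icc)
  }
})

test_that("Kendall's W hits its closed-form anchors and is monotone-invariant", {
  v <- c(3, 1, 4, 1, 5, 9, 2, 6)           # ties present
  expect_equal(kendalls_w(v, v)$W, 1)
  expect_equal(kendalls_w(1:10, 10:1)$W, 0)
  set.seed(81)
  x <- rnorm(50); y <- x + rnorm(50, 0, 0.5)
  expect_equal(kendalls_w(x, y)$W, kendalls_w(exp(x), exp(y))$W)
  # two independent raters concord at ~0.5 on average
  w_bar <- mean(replicate(300, kendalls_w(rnorm(30), rnorm(30))$W))
  expect_equal(w_bar, 0.5, tolerance = 0.03)
})

test_that("the full pipeline populates a coherent report on each branch", {
  set.seed(91)
  # identical measurements: perfect agreement, zero bias
  x <- round(rnorm(100, 500, 30), -1)
  r0 <- run_agreement_pipeline(paired_measurements(x, x, "identity"))
  expect_equal(r0$accuracy, 0)
  expect_equal(r0$precision, 0)
  expect_equal(r0$coefficient, 1)
  # normal data with a proportional bias takes the parametric-corrected branch
  ref <- rnorm(500, 100, 10)
  test <- ref + 0.2 * ref + rnorm(500, 0, 2)
  r1 <- run_agreement_pipeline(paired_measurements(ref, test, "prop"))
  expect_true(r1$normal_d)
  expect_lt(r1$prop_bias_p, 0.05)
  expect_equal(r1$loa_method, "parametric-corrected")
  expect_match(r1$coefficient_method, "ICC")
  # grid-discretised, tied data takes the non-parametric branch
  ref2 <- round(rexp(400, 1 / 80), -1) + 400
  test2 <- ref2 + round(rnorm(400, 0, 12), -1)
  r2 <- run_agreement_pipeline(paired_measurements(ref2, test2, "ties"))
  expect_false(r2$normal_d && r2$normal_both)
  expect_equal(r2$coefficient_method, "Kendall's W")
  for (f in c("accuracy", "precision", "fixed_bias_p", "prop_bias_r",
              "prop_bias_p", "coefficient")) {
    expect_true(is.finite(r2[[f]]), info = f)
  }
  # the limit lines bracket the PA line
  expect_lte(r2$loa_lower[["intercept"]], r2$pa_line[["intercept"]])
  expect_gte(r2$loa_upper[["intercept"]], r2$pa_line[["intercept"]])
})
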