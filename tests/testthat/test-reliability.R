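test_that("typical error matches its closed form and its simulation limit", {
  x <- c(10, 12, 14, 16)
  expect_equal(typical_error(x, x), 0)
  expect_equal(typical_error(x + c(1, -1, 1, -1), x),
               sd(c(1, -1, 1, -1)) / sqrt(2), tolerance = 1e-12)
  expect_equal(typical_error(x + c(1, -1, 1, -1), x), 0.8165, tolerance = 1e-4)
  # with independent noise of SD sigma in each session, TE estimates sigma
  set.seed(501)
  sigma <- 2.5
  truth <- rnorm(1e4, 100, 10)
  te <- typical_error(truth + rnorm(1e4, 0, sigma), truth + rnorm(1e4, 0, sigma))
  expect_lt(abs(te - sigma) / sigma, 0.05)
  expect_error(typical_error(1, numeric(0)), "paired")
})

test_that("CV% ratio and log methods evaluate their formulas", {
  set.seed(502)
  a <- rnorm(12, 100, 6); b <- rnorm(12, 100, 6)
  expect_equal(cv_percent(a, b), 100 * typical_error(a, b) / mean(c(a, b)),
               tolerance = 1e-12)
  expect_equal(cv_percent(a, a), 0)
  # log method, hand formula
  t1 <- c(100, 200); t2 <- c(110, 220)
  expect_equal(cv_percent(t1, t2, "log"),
               100 * (exp(sd(log(t1) - log(t2)) / sqrt(2)) - 1), tolerance = 1e-12)
  expect_error(cv_percent(c(-1, 2, 3), c(1, 2, 3), "log"), "positive")
})

test_that("ICC forms match hand-computed variance components and aov mean squares", {
  x <- c(1, 2, 3, 4)
  expect_equal(icc(x, x, "ICC2_1"), 1)
  expect_equal(icc(x, x, "ICC3_1"), 1)
  # uniform +1 shift: perfect consistency, penalised absolute agreement
  # hand oracle: MSB = 10/3, MSC = 2, MSE = 0 -> ICC(2,1) = (10/3)/(10/3 + 1)
  expect_equal(icc(x, x + 1, "ICC3_1"), 1)
  expect_equal(icc(x, x + 1, "ICC2_1"), 10 / 13, tolerance = 1e-12)

  set.seed(503)
  a <- rnorm(10, 50, 8); b <- a + rnorm(10, 1, 3)
  ms <- chrtest:::icc_mean_squares(a, b)
  long <- data.frame(y = c(a, b),
                     subject = factor(rep(1:10, 2)),
                     session = factor(rep(1:2, each = 10)))
  tab <- anova(lm(y ~ subject + session, data = long))
  expect_equal(ms$msb, tab["subject", "Mean Sq"], tolerance = 1e-9)
  expect_equal(ms$msc, tab["session", "Mean Sq"], tolerance = 1e-9)
  expect_equal(ms$mse, tab["Residuals", "Mean Sq"], tolerance = 1e-9)
})

test_that("ICC estimates converge to the variance-ratio truth and to 0 for noise", {
  set.seed(504)
  sb <- 2; se <- 1   # truth: 4 / 5
  truth <- rnorm(500, 0, sb)
  est <- icc(truth + rnorm(500, 0, se), truth + rnorm(500, 0, se), "ICC2_1")
  expect_lt(abs(est - sb^2 / (sb^2 + se^2)), 0.05)
  indep <- icc(rnorm(2000), rnorm(2000), "ICC3_1")
  expect_lt(abs(indep), 0.08)
})

test_that("ICC degeneracies are flagged, not silently computed", {
  expect_warning(v <- icc(rep(3, 4), rep(3, 4)), "undefined")
  expect_true(is.nan(v))
  expect_warning(icc(c(1, 2), c(1.2, 2.1)), "fewer than 3")
})

test_that("SEM and MDC closed forms and their exact ratio", {
  expect_equal(sem(10, 0.84), 4)
  expect_equal(sem(10, 1), 0)
  expect_equal(sem(16.6, 0.75), 8.3)
  expect_equal(mdc(4), 4 * 1.96 * sqrt(2), tolerance = 1e-12)
  expect_equal(mdc(4), 11.0872, tolerance = 1e-4)
  expect_equal(mdc(0), 0)
  expect_equal(mdc(1), 2.7718, tolerance = 1e-4)
  expect_error(sem(10, 1.2), "icc")
  expect_error(mdc(-1), ">= 0")
})

test_that("paired comparisons report t-test p, Cohen's d, and the literal bands", {
  x <- c(10, 11, 13, 15, 18)
  same <- paired_effect(x, x)
  expect_equal(same$effect_size_d, 0)
  expect_equal(same$effect_band, "small")
  expect_equal(same$p_value, 1)
  expect_true(same$degenerate)

  set.seed(505)
  a <- rnorm(12, 100, 5); b <- rnorm(12, 103, 5)
  pe <- paired_effect(a, b)
  expect_equal(pe$p_value, t.test(a, b, paired = TRUE)$p.value, tolerance = 1e-12)
  expect_equal(pe$effect_size_d,
               mean(a - b) / sqrt((var(a) + var(b)) / 2), tolerance = 1e-12)
  dz <- paired_effect(a, b, d_method = "dz")
  expect_equal(dz$effect_size_d, mean(a - b) / sd(a - b), tolerance = 1e-12)

  # band thresholds, boundaries inclusive as printed, sign ignored
  expect_equal(effect_band(0.20), "small")
  expect_equal(effect_band(0.35), "moderate")
  expect_equal(effect_band(0.50), "moderate")
  expect_equal(effect_band(-0.80), "large")
  expect_equal(effect_band(0.85), "very_large")

  shifted <- paired_effect(x + 2, x)   # zero-variance nonzero-mean differences
  expect_true(shifted$degenerate)
  expect_equal(shifted$p_value, 0)
})

test_that("reliability reports satisfy their internal identities on random data", {
  set.seed(506)
  for (i in 1:20) {
    truth <- rnorm(15, 100, 12)
    a <- truth + rnorm(15, 0, 4); b <- truth + rnorm(15, 0, 4)
    rr <- reliability_report(a, b, metric = "x")
    expect_equal(rr$sem, rr$sd_used * sqrt(1 - rr$icc), tolerance = 1e-9)
    expect_equal(rr$mdc, rr$sem * 1.96 * sqrt(2), tolerance = 1e-9)
    if (rr$sem > 0) expect_equal(rr$mdc / rr$sem, 1.96 * sqrt(2), tolerance = 1e-12)
    expect_lte(rr$icc, 1)
    expect_gte(rr$te, 0)
    expect_gte(rr$mdc, rr$sem)
    # the consistency form exceeds absolute agreement whenever the session
    # effect is estimable above the error (MSC >= MSE); with 2 sessions the
    # sample session effect can dip below the error term by chance, in which
    # case the ICC(2,1) denominator correction flips sign
    shift <- reliability_report(a + 3, b, metric = "x")
    ms <- chrtest:::icc_mean_squares(a + 3, b)
    if (ms$msc >= ms$mse) expect_gte(shift$icc3_1, shift$icc2_1)
  }
})

test_that("TE is shift-invariant; ratio-method CV% is not", {
  set.seed(507)
  a <- rnorm(10, 50, 5); b <- rnorm(10, 50, 5)
  expect_equal(typical_error(a + 100, b + 100), typical_error(a, b),
               tolerance = 1e-12)
  expect_false(isTRUE(all.equal(cv_percent(a + 100, b + 100), cv_percent(a, b))))
})

test_that("identical sessions collapse the whole battery to its degenerate values", {
  x <- c(3, 5, 8, 13, 21)
  rr <- reliability_report(x, x)
  expect_equal(rr$te, 0)
  expect_equal(rr$icc, 1)
  expect_equal(rr$sem, 0)
  expect_equal(rr$mdc, 0)
  expect_equal(rr$cv_percent, 0)
})
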