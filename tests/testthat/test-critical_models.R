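test_that("collinear efforts are recovered exactly by both parameterizations", {
  fit <- fit_critical_speed(c(400, 800, 1200), c(250, 500, 750))
  expect_equal(fit$slope, 1.6, tolerance = 1e-12)
  expect_equal(fit$intercept, 0, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1)

  t <- (c(400, 800, 1200) - 50) / 1.2   # d = 1.2 t + 50
  fit2 <- fit_critical_speed(c(400, 800, 1200), t)
  expect_equal(fit2$slope, 1.2, tolerance = 1e-12)
  expect_equal(fit2$intercept, 50, tolerance = 1e-9)

  inv <- fit_inverse_time_form(c(400, 800, 1200), t)
  expect_equal(inv$slope, fit2$slope, tolerance = 1e-9)
  expect_equal(inv$intercept, fit2$intercept, tolerance = 1e-7)
  inv0 <- fit_inverse_time_form(c(400, 800, 1200), c(250, 500, 750))  # d = 1.6 t
  expect_equal(inv0$slope, 1.6, tolerance = 1e-9)
  expect_equal(inv0$intercept, 0, tolerance = 1e-7)
})

test_that("heartbeats-time fits recover constructed lines and report CHR in beats/min", {
  fit <- fit_critical_hr(c(670, 1320, 2100), c(300, 600, 960))  # HB = 130 t_min + 20
  expect_equal(fit$slope, 130, tolerance = 1e-9)
  expect_equal(fit$intercept, 20, tolerance = 1e-9)
  prop <- fit_critical_hr(140 * c(300, 600, 960) / 60, c(300, 600, 960))
  expect_equal(prop$slope, 140, tolerance = 1e-9)
  expect_equal(prop$intercept, 0, tolerance = 1e-9)
})

test_that("OLS matches the closed-form normal-equations oracle on random instances", {
  set.seed(401)
  for (i in 1:50) {
    t <- sort(runif(3, 200, 1000))
    d <- 1.2 * t + 50 + rnorm(3, 0, 5)
    fit <- fit_critical_speed(d, t)
    oracle <- ols_oracle(t, d)
    expect_equal(fit$slope, unname(oracle["slope"]), tolerance = 1e-9)
    expect_equal(fit$intercept, unname(oracle["intercept"]), tolerance = 1e-9)
    hb <- 110 * t / 60 + 20 + rnorm(3, 0, 10)
    fhr <- fit_critical_hr(hb, t)
    oracle_hr <- ols_oracle(t / 60, hb)
    expect_equal(fhr$slope, unname(oracle_hr["slope"]), tolerance = 1e-9)
  }
})

test_that("units are consistent: CS in m/min is exactly 60x CS in m/s", {
  set.seed(402)
  t <- sort(runif(3, 200, 1000))
  fit <- fit_critical_speed(1.3 * t + 40 + rnorm(3, 0, 3), t)
  expect_identical(fit$slope_m_per_min, fit$slope * 60)
})

test_that("degenerate fit inputs raise errors; 2-point fits warn", {
  expect_error(fit_critical_speed(400, 250), "at least 2")
  suppressWarnings(expect_error(fit_critical_speed(c(400, 800), c(300, 300)),
                                "singular"))
  expect_error(fit_critical_speed(c(400, -800, 1200), c(1, 2, 3)), "positive")
  expect_warning(fit_critical_speed(c(400, 800), c(250, 500)), "2 efforts")
})

test_that("predict_time inverts the fitted line and is strictly monotone", {
  fit <- fit_critical_speed(c(400, 800, 1200), c(250, 500, 750))
  expect_equal(predict_time(fit, 800), 500, tolerance = 1e-9)
  t <- (c(400, 800, 1200) - 50) / 1.2
  fit2 <- fit_critical_speed(c(400, 800, 1200), t)
  expect_equal(predict_time(fit2, 1200), (1200 - 50) / 1.2, tolerance = 1e-9)
  d_grid <- seq(100, 2000, by = 100)
  expect_true(all(diff(predict_time(fit2, d_grid)) > 0))
  expect_error(predict_time(fit2, 40), "exceed")
})

test_that("intensity zones derive from the CHR with a tolerance band", {
  fit <- fit_critical_hr(c(670, 1320, 2100), c(300, 600, 960))  # CHR 130
  expect_equal(prescribe_intensity(fit, 140)$zone, "above_chr")
  expect_equal(prescribe_intensity(fit, 130)$zone, "at_chr")
  expect_equal(prescribe_intensity(fit, 120)$zone, "below_chr")
  expect_equal(prescribe_intensity(fit, 134)$zone, "above_chr")
  expect_equal(prescribe_intensity(fit, 134, tolerance_bpm = 5)$zone, "at_chr")
  sp <- fit_critical_speed(c(400, 800, 1200), c(250, 500, 750))
  expect_error(prescribe_intensity(sp, 130), "hr-variant")
})

test_that("relative intensity uses the selected age-predicted HRmax formula", {
  expect_equal(relative_intensity(104, 60, "220-age"), 65)
  expect_equal(relative_intensity(110.5, 65, "208-0.7age"), 68)  # HRmax 162.5
  expect_equal(relative_intensity(110.5, 65),
               relative_intensity(110.5, 65, "208-0.7age"))
  expect_error(relative_intensity(110, 10), "18")
  expect_error(relative_intensity(110, 60, "weird"), "formula")
})

test_that("fitted parameters converge to the truth as timing noise vanishes", {
  set.seed(403)
  p <- quiet_participant(timing_noise_cv = 1e-4)
  est <- replicate(50, {
    trials <- lapply(c(400, 800, 1200), simulate_effort, participant = p)
    s <- summarize_efforts(trials)
    fit_critical_speed(s$distance_m, s$time_s)$slope
  })
  expect_lt(abs(mean(est) - 1.2) / 1.2, 0.001)  # bias < 0.1% at CV 0.01%
})
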