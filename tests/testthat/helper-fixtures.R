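# shared helpers for building tiny in-code fixtures

constant_hr_trial <- function(hr = 120, time_s = 300, distance_m = 400,
                              interval_s = 5, session = "test", id = "p1") {
  t <- seq(interval_s, by = interval_s,
           length.out = ceiling(time_s / interval_s))
  effort_trial(id, session, distance_m, time_s,
               hr_series(t, rep(hr, length(t)), interval_s = interval_s))
}

# closed-form normal-equations OLS, the independent oracle for the fits
ols_oracle <- function(x, y) {
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  c(intercept = mean(y) - slope * mean(x), slope = slope)
}

quiet_participant <- function(...) {
  args <- list(...)
  defaults <- list(true_cs_m_per_s = 1.2, true_dprime_m = 30,
                   true_chr_bpm = 110, true_hbprime_beats = 20,
                   timing_noise_cv = 0, hb_noise_cv = 0)
  do.call(simulated_participant, utils::modifyList(defaults, args))
}
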