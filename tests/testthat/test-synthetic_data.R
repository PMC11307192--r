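test_that("zero-noise efforts land exactly on both truth lines", {
  p <- quiet_participant(true_cs_m_per_s = 1.6, true_dprime_m = 0,
                         true_chr_bpm = 120, true_hbprime_beats = 0)
  tr <- simulate_effort(p, 400)
  expect_equal(tr$time_s, 250, tolerance = 1e-12)
  expect_equal(total_heartbeats(tr), 120 * 250 / 60, tolerance = 1e-9)

  p2 <- quiet_participant()
  tr2 <- simulate_effort(p2, 800)
  expect_equal(tr2$time_s, (800 - 30) / 1.2, tolerance = 1e-12)
  # heartbeat conservation: emitted samples integrate to the truth-line HB
  expect_equal(total_heartbeats(tr2),
               110 * tr2$time_s / 60 + 20, tolerance = 1e-9)
  expect_error(simulate_effort(p2, 20), "exceed")
})

test_that("the HR trace keeps the rise-and-plateau kinetic shape", {
  p <- quiet_participant(tau_s = 30, drift_bpm_per_min = 0)
  tr <- simulate_effort(p, 1200)
  hr <- tr$samples$hr_bpm
  expect_true(all(diff(hr) >= -1e-9))            # monotone on-response
  expect_lt(hr[1], hr[length(hr)])
  # with no drift, the trace approaches a plateau: late increments shrink
  n <- length(hr)
  expect_lt(abs(hr[n] - hr[n - 1]), abs(hr[2] - hr[1]))
})

test_that("cohort simulation is deterministic in the seed and has the right layout", {
  cfg <- simulation_config(n_participants = 15, seed = 42)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_equal(length(a$trials), 15 * 3 * 2)
  expect_identical(fit_cohort(a), fit_cohort(b))
  expect_identical(a$participants, b$participants)
  expect_identical(a$trials[[7]]$samples$hr_bpm, b$trials[[7]]$samples$hr_bpm)
  d <- simulate_cohort(simulation_config(n_participants = 15, seed = 43))
  expect_false(identical(fit_cohort(a)$cs_m_per_s, fit_cohort(d)$cs_m_per_s))
  # each participant x session covers each distance exactly once
  s <- summarize_efforts(a$trials)
  counts <- table(s$participant_id, s$session, s$distance_m)
  expect_true(all(counts == 1))
})

test_that("zero-noise cohorts recover every participant's CS and CHR exactly", {
  cfg <- simulation_config(n_participants = 6, seed = 9,
                           timing_noise_cv = 0, hb_noise_cv = 0)
  coh <- simulate_cohort(cfg)
  fits <- fit_cohort(coh)
  m <- merge(fits, coh$participants[c("id", "true_cs_m_per_s", "true_chr_bpm")],
             by.x = "participant_id", by.y = "id")
  expect_lt(max(abs(m$cs_m_per_s - m$true_cs_m_per_s)), 1e-6)
  expect_lt(max(abs(m$chr_bpm - m$true_chr_bpm)), 1e-6)
  expect_true(all(m$r2_speed > 1 - 1e-9))
})

test_that("empirical timing noise matches the configured CV", {
  set.seed(801)
  p <- quiet_participant(timing_noise_cv = 0.02)
  times <- replicate(4000, simulate_effort(p, 400)$time_s)
  emp_cv <- sd(times) / mean(times)
  expect_lt(abs(emp_cv - 0.02) / 0.02, 0.10)
})

test_that("estimation error grows monotonically with timing noise", {
  rmse_at <- function(cv, reps = 60) {
    errs <- replicate(reps, {
      p <- quiet_participant(timing_noise_cv = cv)
      trials <- lapply(c(400, 800, 1200), simulate_effort, participant = p)
      s <- summarize_efforts(trials)
      fit_critical_speed(s$distance_m, s$time_s)$slope - 1.2
    })
    sqrt(mean(errs^2))
  }
  set.seed(802)
  rmse <- vapply(c(0.005, 0.02, 0.08), rmse_at, numeric(1))
  expect_true(all(diff(rmse) > 0))
  expect_lt(rmse[1], 0.02)
})

test_that("training simulation applies per-distance reductions with HB proportional to time", {
  cfg <- simulation_config(n_participants = 4, seed = 5,
                           timing_noise_cv = 0, hb_noise_cv = 0)
  coh <- simulate_cohort(cfg, design = "experiment2")
  s <- summarize_efforts(coh$trials)
  for (i in seq_len(4)) {
    id <- coh$participants$id[i]
    for (d in c(400, 800, 1200)) {
      pre <- s[s$participant_id == id & s$session == "pre" & s$distance_m == d, ]
      post <- s[s$participant_id == id & s$session == "post" & s$distance_m == d, ]
      red <- unname(c("400" = 0.08, "800" = 0.04, "1200" = 0.02)[as.character(d)])
      expect_equal(post$time_s, pre$time_s * (1 - red), tolerance = 1e-9)
      # HB falls proportionally to time: mean HR unchanged
      expect_equal(post$total_hb_beats / post$time_s,
                   pre$total_hb_beats / pre$time_s, tolerance = 1e-9)
    }
  }
})

test_that("config and participant invariants are enforced", {
  expect_error(simulation_config(distances_m = c(400, 400, 800)), "distinct")
  expect_error(simulation_config(n_participants = 0), ">= 1")
  expect_error(simulated_participant(1.2, 30, 200, 20, hr_rest_bpm = 70,
                                     hr_amplitude_bpm = 40), "steady-state")
  expect_error(simulated_participant(1.2, 30, 110, 20, tau_s = 300), "tau_s")
})
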