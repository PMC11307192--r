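# Cohort simulator with known ground truth. Every pipeline stage (effort
# metrics, model fits, reliability battery, training effects) is validated
# against cohorts generated here, because no raw per-effort recordings are
# publicly deposited for this protocol.

#' Ground-truth parameters of one simulated participant
#'
#' @param true_cs_m_per_s critical speed (m/s).
#' @param true_dprime_m distance reserve D' (m).
#' @param true_chr_bpm critical heart rate (beats/min).
#' @param true_hbprime_beats heartbeat reserve HB' (beats).
#' @param hr_rest_bpm resting/baseline HR at effort start.
#' @param hr_amplitude_bpm amplitude of the mono-exponential HR
#'   on-response; the quasi-steady-state HR before drift is
#'   `hr_rest + hr_amplitude`, which must exceed `true_chr_bpm`.
#' @param tau_s time constant of the on-response, in (10, 120) s.
#' @param drift_bpm_per_min slow upward HR drift.
#' @param timing_noise_cv coefficient of variation of the multiplicative
#'   lognormal noise on effort times.
#' @param hb_noise_cv coefficient of variation of the multiplicative noise
#'   on total heartbeats (measurement/biological noise independent of the
#'   timing noise).
#' @return list of class `"simulated_participant"`.
#' @export
simulated_participant <- function(true_cs_m_per_s, true_dprime_m,
                                  true_chr_bpm, true_hbprime_beats,
                                  hr_rest_bpm = 75, hr_amplitude_bpm = 50,
                                  tau_s = 40, drift_bpm_per_min = 1,
                                  timing_noise_cv = 0.02, hb_noise_cv = 0.02) {
  for (nm in c("true_cs_m_per_s", "true_chr_bpm",
               "hr_rest_bpm", "hr_amplitude_bpm", "tau_s"))
    stop_if_not_number(get(nm), nm, positive = TRUE)
  stop_if_not_number(true_dprime_m, "true_dprime_m", nonneg = TRUE)
  stop_if_not_number(true_hbprime_beats, "true_hbprime_beats", nonneg = TRUE)
  stop_if_not_number(drift_bpm_per_min, "drift_bpm_per_min", nonneg = TRUE)
  stop_if_not_number(timing_noise_cv, "timing_noise_cv", nonneg = TRUE)
  stop_if_not_number(hb_noise_cv, "hb_noise_cv", nonneg = TRUE)
  if (tau_s <= 10 || tau_s >= 120)
    stop("tau_s must lie in (10, 120) seconds", call. = FALSE)
  if (true_chr_bpm >= hr_rest_bpm + hr_amplitude_bpm)
    stop("true_chr_bpm must be below the steady-state HR (rest + amplitude)", call. = FALSE)
  structure(list(true_cs_m_per_s = true_cs_m_per_s,
                 true_dprime_m = true_dprime_m,
                 true_chr_bpm = true_chr_bpm,
                 true_hbprime_beats = true_hbprime_beats,
                 hr_rest_bpm = hr_rest_bpm,
                 hr_amplitude_bpm = hr_amplitude_bpm,
                 tau_s = tau_s,
                 drift_bpm_per_min = drift_bpm_per_min,
                 timing_noise_cv = timing_noise_cv,
                 hb_noise_cv = hb_noise_cv),
            class = "simulated_participant")
}

#' Simulation configuration
#'
#' Defaults describe a slow-walking clinical cohort performing three
#' randomly ordered efforts of 400/800/1200 m per session, HR recorded as
#' 5-s averages: mean critical speed 1.2 m/s (so the 1200 m effort takes
#' about 16 min, the 400 m about 5 min), between-participant CS spread 15%
#' of the mean, critical HR set as a fraction (0.695) of the age-predicted
#' maximal HR at the cohort's mean age, 2% multiplicative timing and
#' heartbeat noise re-sampled at retest, and an 8-week training effect of
#' -8%/-4%/-2% on the 400/800/1200 m times with heartbeats reduced
#' proportionally to time at unchanged mean HR.
#'
#' @param n_participants cohort size (default 15).
#' @param distances_m effort distances (default c(400, 800, 1200)).
#' @param seed integer RNG seed; fixed seed implies byte-identical output.
#' @param cs_mean,cs_sd between-participant critical-speed distribution (m/s).
#' @param dprime_mean,dprime_sd distance-reserve distribution (m).
#' @param chr_fraction_of_hrmax CHR as a fraction of age-predicted HRmax.
#' @param age_mean_years cohort mean age used for the HRmax anchor.
#' @param hbprime_mean,hbprime_sd heartbeat-reserve distribution (beats).
#' @param timing_noise_cv,hb_noise_cv multiplicative noise CVs per effort.
#' @param training_time_reduction_percent named per-distance percentage
#'   reductions of effort time after training.
#' @param sampling_interval_s HR recording interval (default 5 s).
#' @param hr_ceiling_bpm cap applied to the kinetic HR profile.
#' @return list of class `"simulation_config"`.
#' @export
simulation_config <- function(n_participants = 15,
                              distances_m = c(400, 800, 1200),
                              seed = 1L,
                              cs_mean = 1.2, cs_sd = 0.18,
                              dprime_mean = 30, dprime_sd = 10,
                              chr_fraction_of_hrmax = 0.695,
                              age_mean_years = 72,
                              hbprime_mean = 20, hbprime_sd = 8,
                              timing_noise_cv = 0.02, hb_noise_cv = 0.02,
                              training_time_reduction_percent =
                                c("400" = 8, "800" = 4, "1200" = 2),
                              sampling_interval_s = 5,
                              hr_ceiling_bpm = 190) {
  if (n_participants < 1) stop("n_participants must be >= 1", call. = FALSE)
  if (length(distances_m) < 2 || any(distances_m <= 0) ||
      anyDuplicated(distances_m))
    stop("distances_m must be >= 2 positive distinct values", call. = FALSE)
  stop_if_not_number(seed, "seed")
  structure(list(n_participants = as.integer(n_participants),
                 distances_m = sort(distances_m),
                 seed = as.integer(seed),
                 cs_mean = cs_mean, cs_sd = cs_sd,
                 dprime_mean = dprime_mean, dprime_sd = dprime_sd,
                 chr_fraction_of_hrmax = chr_fraction_of_hrmax,
                 age_mean_years = age_mean_years,
                 hbprime_mean = hbprime_mean, hbprime_sd = hbprime_sd,
                 timing_noise_cv = timing_noise_cv,
                 hb_noise_cv = hb_noise_cv,
                 training_time_reduction_percent = training_time_reduction_percent,
                 sampling_interval_s = sampling_interval_s,
                 hr_ceiling_bpm = hr_ceiling_bpm),
            class = "simulation_config")
}

#' Draw the ground-truth parameters of a simulated cohort
#'
#' @param config a [simulation_config()]; the caller is responsible for
#'   seeding the RNG (as [simulate_cohort()] does).
#' @return data frame with one row per participant: id plus every
#'   [simulated_participant()] field.
#' @export
draw_participants <- function(config) {
  n <- config$n_participants
  hrmax <- 208 - 0.7 * config$age_mean_years
  cs <- pmax(0.4, stats::rnorm(n, config$cs_mean, config$cs_sd))
  dp <- pmax(5, stats::rnorm(n, config$dprime_mean, config$dprime_sd))
  chr <- pmax(60, stats::rnorm(n, config$chr_fraction_of_hrmax * hrmax,
                               0.08 * config$chr_fraction_of_hrmax * hrmax))
  hbp <- pmax(1, stats::rnorm(n, config$hbprime_mean, config$hbprime_sd))
  rest <- stats::rnorm(n, 75, 5)
  plateau <- chr + pmax(5, stats::rnorm(n, 20, 5))  # steady state sits above CHR
  data.frame(id = sprintf("sim%02d", seq_len(n)),
             true_cs_m_per_s = cs,
             true_dprime_m = dp,
             true_chr_bpm = chr,
             true_hbprime_beats = hbp,
             hr_rest_bpm = rest,
             hr_amplitude_bpm = pmax(10, plateau - rest),
             tau_s = stats::runif(n, 25, 60),
             drift_bpm_per_min = stats::runif(n, 0.5, 2),
             timing_noise_cv = config$timing_noise_cv,
             hb_noise_cv = config$hb_noise_cv,
             stringsAsFactors = FALSE)
}

participant_from_row <- function(row) {
  simulated_participant(true_cs_m_per_s = row$true_cs_m_per_s,
                        true_dprime_m = row$true_dprime_m,
                        true_chr_bpm = row$true_chr_bpm,
                        true_hbprime_beats = row$true_hbprime_beats,
                        hr_rest_bpm = row$hr_rest_bpm,
                        hr_amplitude_bpm = row$hr_amplitude_bpm,
                        tau_s = row$tau_s,
                        drift_bpm_per_min = row$drift_bpm_per_min,
                        timing_noise_cv = row$timing_noise_cv,
                        hb_noise_cv = row$hb_noise_cv)
}

#' Simulate one maximal walking effort
#'
#' The effort time comes from the participant's distance-time truth line,
#' `t = (d - D') / CS`, times a mean-one lognormal factor with the
#' configured timing CV. The total-heartbeat target comes from the
#' heartbeats-time truth line evaluated at the realized time,
#' `HB = CHR * t_min + HB'`, times an independent mean-one lognormal
#' factor. The HR trace has the mono-exponential-plus-drift shape
#' `rest + amplitude * (1 - exp(-t/tau)) + drift * t/60` (capped at the
#' ceiling), uniformly rescaled so the emitted 5-s averages integrate
#' exactly to the heartbeat target: the kinetic profile sets the shape,
#' the truth line sets the area. At zero noise the fitted CS and CHR
#' therefore equal the ground truth exactly.
#'
#' @param participant a [simulated_participant()] (or one row of
#'   [draw_participants()] coerced via its fields).
#' @param distance_m effort distance, must exceed the distance reserve D'.
#' @param session session label for the emitted trial.
#' @param participant_id identifier for the emitted trial.
#' @param interval_s HR sampling interval (default 5 s).
#' @param hr_ceiling_bpm cap on the kinetic profile (default 190).
#' @param time_scale deterministic multiplier on the effort time (used for
#'   training effects; default 1).
#' @param hb_scale deterministic multiplier on the heartbeat target
#'   relative to the unscaled truth line (default `time_scale`, i.e.
#'   heartbeats fall proportionally to time at unchanged mean HR).
#' @return an [effort_trial].
#' @export
simulate_effort <- function(participant, distance_m, session = "test",
                            participant_id = "sim01", interval_s = 5,
                            hr_ceiling_bpm = 190, time_scale = 1,
                            hb_scale = time_scale) {
  p <- participant
  if (distance_m <= p$true_dprime_m)
    stop(sprintf("distance (%g m) must exceed the participant's D' (%g m)",
                 distance_m, p$true_dprime_m), call. = FALSE)
  t_det <- (distance_m - p$true_dprime_m) / p$true_cs_m_per_s * time_scale
  time_s <- t_det * rlnorm_factor(1, p$timing_noise_cv)
  t_unscaled_min <- time_s / time_scale / 60
  hb_target <- (p$true_chr_bpm * t_unscaled_min + p$true_hbprime_beats) *
    hb_scale * rlnorm_factor(1, p$hb_noise_cv)
  t_i <- seq(interval_s, by = interval_s,
             length.out = max(1L, ceiling(time_s / interval_s)))
  shape <- p$hr_rest_bpm +
    p$hr_amplitude_bpm * (1 - exp(-t_i / p$tau_s)) +
    p$drift_bpm_per_min * t_i / 60
  shape <- pmin(shape, hr_ceiling_bpm)
  hr_i <- shape * hb_target / (mean(shape) * time_s / 60)
  effort_trial(participant_id, session, distance_m, time_s,
               hr_series(t_i, hr_i, interval_s = interval_s))
}

#' Simulate a full study cohort
#'
#' Generates per-participant trials for either the test-retest design
#' (each distance once in the `test` and once in the `retest` session,
#' order randomized within each session, retest re-sampling only the
#' noise) or the pre/post training design (the `post` session applies the
#' configured per-distance time reductions, with total heartbeats reduced
#' proportionally to time at unchanged mean HR). A master seed drives
#' per-participant substreams, so output is byte-identical for a fixed
#' config.
#'
#' @param config a [simulation_config()].
#' @param design `"experiment1"` (test/retest) or `"experiment2"`
#'   (pre/post training).
#' @return list with `participants` (ground-truth data frame), `trials`
#'   (list of [effort_trial]), and `config`.
#' @export
simulate_cohort <- function(config, design = c("experiment1", "experiment2")) {
  design <- match.arg(design)
  set.seed(config$seed)
  participants <- draw_participants(config)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, config$n_participants)
  sessions <- if (design == "experiment1") c("test", "retest") else c("pre", "post")
  red <- config$training_time_reduction_percent
  trials <- list()
  for (i in seq_len(config$n_participants)) {
    set.seed(sub_seeds[i])
    p <- participant_from_row(participants[i, ])
    for (sess in sessions) {
      for (d in sample(config$distances_m)) {   # random effort order
        scale <- 1
        if (design == "experiment2" && sess == "post") {
          r <- red[as.character(d)]
          if (is.na(r)) r <- 0
          scale <- 1 - r / 100
        }
        trials[[length(trials) + 1L]] <-
          simulate_effort(p, d, session = sess,
                          participant_id = participants$id[i],
                          interval_s = config$sampling_interval_s,
                          hr_ceiling_bpm = config$hr_ceiling_bpm,
                          time_scale = scale)
      }
    }
  }
  list(participants = participants, trials = trials, config = config)
}

#' Fit both critical models for every participant and session
#'
#' Convenience driver: summarizes each trial, then fits the distance-time
#' (critical speed) and heartbeats-time (critical HR) lines per
#' participant and session.
#'
#' @param cohort output of [simulate_cohort()], or any list with a
#'   `trials` element of [effort_trial] objects.
#' @return data frame with one row per participant x session: fitted
#'   `cs_m_per_s`, `dprime_m`, `r2_speed`, `chr_bpm`, `hbprime_beats`,
#'   `r2_hr`, plus per-distance `time_<d>` and `hb_<d>` columns.
#' @export
fit_cohort <- function(cohort) {
  summ <- summarize_efforts(cohort$trials)
  keys <- unique(summ[c("participant_id", "session")])
  rows <- lapply(seq_len(nrow(keys)), function(r) {
    sub <- summ[summ$participant_id == keys$participant_id[r] &
                  summ$session == keys$session[r], ]
    sub <- sub[order(sub$distance_m), ]
    fs <- fit_critical_speed(sub$distance_m, sub$time_s)
    fh <- fit_critical_hr(sub$total_hb_beats, sub$time_s)
    base <- data.frame(participant_id = keys$participant_id[r],
                       session = keys$session[r],
                       cs_m_per_s = fs$slope, dprime_m = fs$intercept,
                       r2_speed = fs$r_squared,
                       chr_bpm = fh$slope, hbprime_beats = fh$intercept,
                       r2_hr = fh$r_squared,
                       stringsAsFactors = FALSE)
    for (j in seq_len(nrow(sub))) {
      base[[paste0("time_", sub$distance_m[j])]] <- sub$time_s[j]
      base[[paste0("hb_", sub$distance_m[j])]] <- sub$total_hb_beats[j]
    }
    base
  })
  do.call(rbind, rows)
}

#' The packaged cohort characteristics fixture
#'
#' Returns the 15-participant cohort characteristics table (sex, age,
#' anthropometrics, clinical scores) shipped with the package, with the
#' training-experiment membership flag set for participants
#' 1, 4, 5, 8, 10, 12, 13 and 15.
#'
#' @return a `"cohort"` data frame with 15 rows.
#' @export
make_table1_fixture <- function() {
  df <- data.frame(
    id = 1:15,
    sex = c("M","M","F","M","F","F","M","F","M","M","M","F","M","F","M"),
    age_years = c(64,76,78,68,67,77,83,78,72,82,67,66,61,66,74),
    height_m = c(1.69,1.65,1.45,1.65,1.57,1.40,1.61,1.46,1.60,1.67,1.74,1.58,1.74,1.58,1.67),
    mass_kg = c(74.0,58.0,44.4,72.0,69.8,48.2,70.0,48.8,65.0,81.6,97.0,49.0,87.0,49.0,86.0),
    updrs2 = c(8,14,7,12,16,13,6,10,10,13,14,9,6,8,14),
    updrs3 = c(25,31,23,48,33,52,20,24,39,31,33,27,20,29,24),
    hy = c(2,2,2,2,2,2.5,2,2,2.5,2,2,2.5,1.5,2,2),
    mmse = c(29,27,27,24,26,21,30,28,26,28,30,25,29,29,27),
    tmt_a_s = c(37.72,82.60,53.35,67.84,37.21,227.64,76.63,22.92,67.84,79.64,45.00,27.22,66.29,76.00,49.76),
    tmt_b_s = c(73.22,146.08,210.05,153.29,143.98,153.29,173.19,205.67,153.29,155.09,109.94,61.91,168.38,153.29,238.69),
    tug_s = c(5.22,7.03,6.88,4.96,6.22,7.60,7.37,8.27,11.36,6.39,6.12,5.42,7.30,5.81,7.57),
    in_experiment2 = seq_len(15) %in% c(1,4,5,8,10,12,13,15),
    stringsAsFactors = FALSE)
  validate_cohort(df)
}
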