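#' Total heartbeats of an effort
#'
#' The total number of heartbeats (HB) expended during an effort is the
#' arithmetic mean of the recorded HR window-averages multiplied by the
#' effort duration in minutes. HB is the internal-load analogue of
#' distance: plotting HB against effort duration gives the heartbeats-time
#' line whose slope is the critical heart rate.
#'
#' @param trial an [effort_trial].
#' @return total heartbeats (beats), a non-negative scalar.
#' @examples
#' s <- hr_series(seq(5, 300, by = 5), rep(120, 60))
#' tr <- effort_trial("p1", "test", 400, 300, s)
#' total_heartbeats(tr)  # 120 b/min for 5 min = 600 beats
#' @export
total_heartbeats <- function(trial) {
  if (!inherits(trial, "effort_trial")) stop("trial must be an effort_trial", call. = FALSE)
  if (nrow(trial$samples) < 1L) stop("effort has no HR samples", call. = FALSE)
  if (trial$time_s <= 0) stop("effort duration must be positive", call. = FALSE)
  mean(trial$samples$hr_bpm) * trial$time_s / 60
}

#' Summarize one walking effort
#'
#' Derives the per-effort quantities used downstream: mean and maximal HR,
#' total heartbeats, mean speed, and whether the effort duration falls in
#' the recommended 3-12 min window for critical-speed testing. Efforts
#' shorter than 3 min are dominated by the distance reserve above critical
#' speed; efforts much longer than 12 min drift below a maximal sustainable
#' pace, and both distort the linear distance-time fit.
#'
#' @param trial an [effort_trial].
#' @param min_duration_min,max_duration_min bounds of the validity window
#'   in minutes (defaults 3 and 12).
#' @return A list of class `"effort_summary"` with fields `participant_id`,
#'   `session`, `distance_m`, `time_s`, `duration_min`, `mean_hr_bpm`,
#'   `max_hr_bpm`, `total_hb_beats`, `mean_speed_m_per_s`, `duration_valid`.
#' @export
summarize_effort <- function(trial, min_duration_min = 3, max_duration_min = 12) {
  hb <- total_heartbeats(trial)
  dur_min <- trial$time_s / 60
  out <- list(participant_id = trial$participant_id,
              session = trial$session,
              distance_m = trial$distance_m,
              time_s = trial$time_s,
              duration_min = dur_min,
              mean_hr_bpm = mean(trial$samples$hr_bpm),
              max_hr_bpm = max(trial$samples$hr_bpm),
              total_hb_beats = hb,
              mean_speed_m_per_s = trial$distance_m / trial$time_s,
              duration_valid = dur_min >= min_duration_min && dur_min <= max_duration_min)
  class(out) <- "effort_summary"
  out
}

#' @export
print.effort_summary <- function(x, ...) {
  cat(sprintf("%g m in %.2f s (%.1f min%s): mean HR %.1f, max HR %.1f b/min, HB %.1f beats, speed %.3f m/s\n",
              x$distance_m, x$time_s, x$duration_min,
              if (x$duration_valid) "" else ", outside 3-12 min window",
              x$mean_hr_bpm, x$max_hr_bpm, x$total_hb_beats, x$mean_speed_m_per_s))
  invisible(x)
}

#' Tabulate effort summaries for a set of trials
#'
#' @param trials list of [effort_trial] objects.
#' @param ... passed to [summarize_effort()].
#' @return data frame with one row per trial.
#' @export
summarize_efforts <- function(trials, ...) {
  rows <- lapply(trials, function(tr) {
    s <- summarize_effort(tr, ...)
    as.data.frame(s[c("participant_id", "session", "distance_m", "time_s",
                      "duration_min", "mean_hr_bpm", "max_hr_bpm",
                      "total_hb_beats", "mean_speed_m_per_s", "duration_valid")],
                  stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
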