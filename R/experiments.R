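# Whole-protocol drivers wiring the stages into the two study designs:
# experiment 1 (test-retest reliability) and experiment 2 (pre/post training).

#' Pair two sessions of per-participant fits
#'
#' @param fits output of [fit_cohort()].
#' @param session_a,session_b session labels to pair (participants present
#'   in only one session are dropped with a message).
#' @return list with data frames `a` and `b`, row-aligned by participant.
#' @export
pair_sessions <- function(fits, session_a, session_b) {
  a <- fits[fits$session == session_a, ]
  b <- fits[fits$session == session_b, ]
  common <- intersect(a$participant_id, b$participant_id)
  dropped <- setdiff(union(a$participant_id, b$participant_id), common)
  if (length(dropped))
    message(sprintf("dropping %d unpaired participant(s): %s",
                    length(dropped), paste(dropped, collapse = ", ")))
  a <- a[match(common, a$participant_id), ]
  b <- b[match(common, b$participant_id), ]
  list(a = a, b = b)
}

#' Test-retest reliability bundle (experiment-1 design)
#'
#' Runs the full reliability battery on the eight protocol metrics: time
#' and total heartbeats at each of the three distances, plus the fitted
#' critical speed and critical heart rate.
#'
#' @param fits output of [fit_cohort()] for a cohort with `test` and
#'   `retest` sessions.
#' @param distances_m the effort distances (default c(400, 800, 1200)).
#' @param ... passed to [reliability_report()] (icc form, cv method, ...).
#' @return named list of [reliability_report()] objects, one per metric.
#' @export
experiment1_reliability <- function(fits, distances_m = c(400, 800, 1200), ...) {
  ps <- pair_sessions(fits, "test", "retest")
  metrics <- c(paste0("time_", distances_m), paste0("hb_", distances_m),
               "cs_m_per_s", "chr_bpm")
  out <- lapply(metrics, function(m) {
    if (!m %in% names(ps$a))
      stop(sprintf("metric %s not present in fits", m), call. = FALSE)
    reliability_report(ps$a[[m]], ps$b[[m]], metric = m, ...)
  })
  names(out) <- metrics
  out
}

#' Pre/post training-effect bundle (experiment-2 design)
#'
#' Applies the adherence filter (when an attendance table is given), then
#' computes paired pre/post effects for effort times, total heartbeats,
#' critical speed and critical heart rate, with optional 6MWT distances.
#'
#' @param fits output of [fit_cohort()] for a cohort with `pre` and `post`
#'   sessions.
#' @param distances_m the effort distances (default c(400, 800, 1200)).
#' @param attendance optional data frame with columns `participant_id` and
#'   `attended`; participants below the adherence threshold are excluded.
#' @param total_sessions,threshold_percent adherence parameters (defaults
#'   16 sessions, 90%).
#' @param sixmwt optional list with paired `pre` and `post` 6MWT distances
#'   (m) for the retained participants.
#' @param d_method passed to [training_effect()].
#' @return list with `effects` (data frame, one row per metric),
#'   `retained_ids`, and `adherence_percent` (of retained participants).
#' @export
experiment2_training <- function(fits, distances_m = c(400, 800, 1200),
                                 attendance = NULL,
                                 total_sessions = TRAINING_SESSIONS_TOTAL,
                                 threshold_percent = 90,
                                 sixmwt = NULL,
                                 d_method = c("pooled", "dz")) {
  d_method <- match.arg(d_method)
  if (!is.null(attendance)) {
    keep <- adherence_filter(attendance$participant_id, attendance$attended,
                             total_sessions, threshold_percent)
    if (!length(keep))
      stop("no participant meets the adherence threshold", call. = FALSE)
    fits <- fits[fits$participant_id %in% keep, ]
    adher <- 100 * attendance$attended[attendance$participant_id %in% keep] /
      total_sessions
  } else {
    keep <- unique(fits$participant_id)
    adher <- NA_real_
  }
  ps <- pair_sessions(fits, "pre", "post")
  metrics <- c(paste0("time_", distances_m), paste0("hb_", distances_m),
               "cs_m_per_s", "chr_bpm")
  units <- c(rep("s", length(distances_m)), rep("beats", length(distances_m)),
             "m/s", "beats/min")
  pp <- stats::setNames(lapply(seq_along(metrics), function(i)
    list(pre = ps$a[[metrics[i]]], post = ps$b[[metrics[i]]],
         units = units[i])), metrics)
  if (!is.null(sixmwt))
    pp$sixmwt_distance <- list(pre = sixmwt$pre, post = sixmwt$post, units = "m")
  list(effects = training_effect_table(pp, d_method = d_method),
       retained_ids = keep,
       adherence_percent = mean(adher))
}
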