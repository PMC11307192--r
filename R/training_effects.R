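# Experiment-2 style sensitivity analysis: paired pre/post comparisons of
# effort times, total heartbeats, CS, CHR and the six-minute walk test.

#' Number of sessions in the reference training program (8 weeks, twice weekly)
#' @export
TRAINING_SESSIONS_TOTAL <- 16L

#' Pre/post training effect for one metric
#'
#' Paired two-sided t-test of post against pre values with Cohen's d and
#' its magnitude band. Sign convention: change = post - pre, so a
#' performance-time improvement is a negative change and a 6MWT distance
#' gain is positive.
#'
#' @param pre,post paired per-participant values before and after the
#'   intervention (equal length, n >= 2).
#' @param metric label for the measurement.
#' @param units measurement units, recorded in the report.
#' @param d_method `"pooled"` (SD pooled over pre and post, default) or
#'   `"dz"` (SD of the change scores).
#' @return list with `metric`, `units`, `n`, `mean_pre`, `mean_post`,
#'   `mean_change`, `percent_change` (100 * mean change / mean pre),
#'   `p_value`, `effect_size_d`, `effect_band`, `direction`
#'   (`"decrease"`, `"increase"`, `"none"`), `degenerate`.
#' @export
training_effect <- function(pre, post, metric = "metric", units = "",
                            d_method = c("pooled", "dz")) {
  check_pairs(pre, post)
  pe <- paired_effect(post, pre, d_method = match.arg(d_method))
  mean_change <- pe$mean_diff               # post - pre
  list(metric = metric, units = units, n = length(pre),
       mean_pre = mean(pre), mean_post = mean(post),
       mean_change = mean_change,
       percent_change = if (mean(pre) != 0) 100 * mean_change / mean(pre) else NA_real_,
       p_value = pe$p_value,
       effect_size_d = pe$effect_size_d,
       effect_band = pe$effect_band,
       direction = if (mean_change < 0) "decrease"
                   else if (mean_change > 0) "increase" else "none",
       degenerate = pe$degenerate)
}

#' Six-minute walk test training effect
#'
#' Same contract as [training_effect()], for paired 6MWT distances in
#' metres; an increase in distance indicates an aerobic-fitness gain.
#'
#' @param pre,post paired 6MWT distances (m) before and after training.
#' @inheritParams training_effect
#' @return see [training_effect()].
#' @export
sixmwt_effect <- function(pre, post, d_method = c("pooled", "dz")) {
  training_effect(pre, post, metric = "sixmwt_distance", units = "m",
                  d_method = match.arg(d_method))
}

#' Filter participants by training attendance
#'
#' Retains the participants whose attendance meets the adherence threshold
#' (default: at least 90% of the training sessions).
#'
#' @param ids participant identifiers.
#' @param attended per-participant count of sessions attended.
#' @param total_sessions total sessions offered (default
#'   [TRAINING_SESSIONS_TOTAL], 16 = 8 weeks x 2/week).
#' @param threshold_percent minimum attendance percentage (default 90).
#' @return character vector of retained participant ids.
#' @export
adherence_filter <- function(ids, attended,
                             total_sessions = TRAINING_SESSIONS_TOTAL,
                             threshold_percent = 90) {
  if (length(ids) != length(attended))
    stop("ids and attended must have the same length", call. = FALSE)
  if (any(attended < 0)) stop("attendance counts must be non-negative", call. = FALSE)
  if (any(attended > total_sessions))
    stop("attendance counts cannot exceed total_sessions", call. = FALSE)
  stop_if_not_number(total_sessions, "total_sessions", positive = TRUE)
  as.character(ids)[100 * attended / total_sessions >= threshold_percent]
}

#' Pre/post effects across a set of metrics
#'
#' @param pre_post named list; each element a list with components `pre`
#'   and `post` (paired vectors) and optionally `units`.
#' @inheritParams training_effect
#' @return data frame with one row per metric.
#' @export
training_effect_table <- function(pre_post, d_method = c("pooled", "dz")) {
  d_method <- match.arg(d_method)
  rows <- lapply(names(pre_post), function(nm) {
    el <- pre_post[[nm]]
    eff <- training_effect(el$pre, el$post, metric = nm,
                           units = if (is.null(el$units)) "" else el$units,
                           d_method = d_method)
    as.data.frame(eff[c("metric", "units", "n", "mean_pre", "mean_post",
                        "mean_change", "percent_change", "p_value",
                        "effect_size_d", "effect_band", "direction")],
                  stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
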