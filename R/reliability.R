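#' Typical error of measurement
#'
#' The within-subject test-retest standard deviation: the sample SD of the
#' difference scores divided by sqrt(2). Under independent measurement
#' noise of SD sigma in each session, TE estimates sigma.
#'
#' @param test,retest paired per-participant values from the two sessions
#'   (equal length, n >= 2).
#' @return typical error, >= 0, in the units of the measurement.
#' @export
typical_error <- function(test, retest) {
  check_pairs(test, retest)
  stats::sd(test - retest) / sqrt(2)
}

check_pairs <- function(test, retest, min_n = 2L) {
  if (length(test) != length(retest))
    stop("test and retest must be paired (equal length)", call. = FALSE)
  if (length(test) < min_n)
    stop(sprintf("at least %d paired observations are required", min_n), call. = FALSE)
  if (anyNA(test) || anyNA(retest))
    stop("paired measurements may not contain missing values", call. = FALSE)
  invisible(NULL)
}

#' Coefficient of variation of the typical error
#'
#' Expresses test-retest noise relative to the magnitude of the
#' measurement. The ratio method divides the typical error by the grand
#' mean of both sessions; the log method (Hopkins) back-transforms the
#' typical error of the log-values: `100 * (exp(sd(diff(log)) / sqrt(2)) - 1)`.
#'
#' @inheritParams typical_error
#' @param method `"ratio"` (default) or `"log"`.
#' @return CV as a percentage.
#' @export
cv_percent <- function(test, retest, method = c("ratio", "log")) {
  method <- match.arg(method)
  check_pairs(test, retest)
  if (method == "ratio") {
    100 * typical_error(test, retest) / mean(c(test, retest))
  } else {
    if (any(test <= 0) || any(retest <= 0))
      stop("log-method CV requires strictly positive values", call. = FALSE)
    100 * (exp(stats::sd(log(test) - log(retest)) / sqrt(2)) - 1)
  }
}

# mean squares of the two-way participant x session layout (k = 2 sessions)
icc_mean_squares <- function(test, retest) {
  n <- length(test)
  k <- 2
  x <- cbind(test, retest)
  grand <- mean(x)
  row_means <- rowMeans(x)
  col_means <- colMeans(x)
  msb <- k * sum((row_means - grand)^2) / (n - 1)            # between participants
  msc <- n * sum((col_means - grand)^2) / (k - 1)            # between sessions
  resid <- x - outer(row_means, rep(1, k)) -
    outer(rep(1, n), col_means) + grand
  mse <- sum(resid^2) / ((n - 1) * (k - 1))                  # interaction/error
  list(n = n, k = k, msb = msb, msc = msc, mse = mse)
}

#' Intraclass correlation coefficient for test-retest data
#'
#' Computes single-measurement ICCs from the two-way participant-by-session
#' variance decomposition: ICC(2,1), the two-way random-effects
#' absolute-agreement form, which penalises a systematic shift between
#' sessions; and ICC(3,1), the two-way mixed-effects consistency form,
#' which does not.
#'
#' @inheritParams typical_error
#' @param form `"ICC2_1"` (absolute agreement, default) or `"ICC3_1"`
#'   (consistency).
#' @return the ICC (<= 1). When the between-participant variance is zero
#'   the ICC is undefined and `NaN` is returned with a warning.
#' @export
icc <- function(test, retest, form = c("ICC2_1", "ICC3_1")) {
  form <- match.arg(form)
  check_pairs(test, retest)
  if (length(test) < 3L)
    warning("ICC with fewer than 3 participants is unstable", call. = FALSE)
  ms <- icc_mean_squares(test, retest)
  if (ms$msb <= 0 && ms$mse <= 0) {
    warning("zero variance everywhere: ICC undefined", call. = FALSE)
    return(NaN)
  }
  if (ms$msb <= ms$mse && ms$msb == 0) {
    warning("no between-participant variance: ICC undefined", call. = FALSE)
    return(NaN)
  }
  val <- switch(form,
    ICC2_1 = (ms$msb - ms$mse) /
      (ms$msb + (ms$k - 1) * ms$mse + ms$k * (ms$msc - ms$mse) / ms$n),
    ICC3_1 = (ms$msb - ms$mse) / (ms$msb + (ms$k - 1) * ms$mse))
  min(val, 1)
}

#' Standard error of measurement
#'
#' `SEM = SD * sqrt(1 - ICC)`, the absolute measurement noise implied by
#' the between-participant spread and the reliability coefficient.
#'
#' @param sd between-participant standard deviation (>= 0), conventionally
#'   pooled over both sessions.
#' @param icc intraclass correlation, <= 1.
#' @return the SEM, in measurement units.
#' @examples
#' sem(10, 0.84)  # 4
#' @export
sem <- function(sd, icc) {
  stop_if_not_number(sd, "sd", nonneg = TRUE)
  if (!is.finite(icc) || icc > 1) stop("icc must be <= 1", call. = FALSE)
  sd * sqrt(1 - icc)
}

#' Minimal detectable change at 95% confidence
#'
#' `MDC = SEM * 1.96 * sqrt(2)`: the smallest individual change that
#' exceeds measurement noise with 95% confidence across two measurements.
#'
#' @param sem standard error of measurement (>= 0).
#' @return the MDC, in measurement units.
#' @export
mdc <- function(sem) {
  stop_if_not_number(sem, "sem", nonneg = TRUE)
  sem * 1.96 * sqrt(2)
}

#' Effect-size band
#'
#' Assigns the magnitude band used throughout the analysis, reading the
#' thresholds literally as upper bounds on |d|: small (<= 0.20), moderate
#' (<= 0.50), large (<= 0.80), very large (> 0.80). Note this inverts the
#' common "large means at least 0.8" phrasing: here 0.80 is the *upper*
#' edge of the large band.
#'
#' @param d Cohen's d (sign ignored).
#' @return one of `"small"`, `"moderate"`, `"large"`, `"very_large"`.
#' @export
effect_band <- function(d) {
  a <- abs(d)
  if (a <= 0.20) "small"
  else if (a <= 0.50) "moderate"
  else if (a <= 0.80) "large"
  else "very_large"
}

#' Paired comparison with effect size
#'
#' Two-sided paired Student's t-test of the two sessions, with Cohen's d
#' and its magnitude band. By default d divides the mean difference by the
#' pooled SD of the two sessions; the `"dz"` variant divides by the SD of
#' the difference scores.
#'
#' @inheritParams typical_error
#' @param d_method `"pooled"` (default) or `"dz"`.
#' @return list with `mean_diff` (test - retest), `p_value`,
#'   `effect_size_d`, `effect_band`, and `degenerate` (TRUE when the
#'   difference scores have zero variance, in which case the p-value is
#'   reported as its limiting value: 1 for a zero mean difference, 0
#'   otherwise).
#' @export
paired_effect <- function(test, retest, d_method = c("pooled", "dz")) {
  d_method <- match.arg(d_method)
  check_pairs(test, retest)
  diffs <- test - retest
  mean_diff <- mean(diffs)
  sd_diff <- stats::sd(diffs)
  sd_pooled <- sqrt((stats::var(test) + stats::var(retest)) / 2)
  degenerate <- sd_diff == 0
  p <- if (degenerate) {
    if (mean_diff == 0) 1 else 0
  } else {
    stats::t.test(test, retest, paired = TRUE)$p.value
  }
  denom <- if (d_method == "pooled") sd_pooled else sd_diff
  d <- if (mean_diff == 0) 0 else if (denom == 0) Inf * sign(mean_diff) else mean_diff / denom
  list(mean_diff = mean_diff, p_value = p, effect_size_d = d,
       effect_band = effect_band(d), degenerate = degenerate)
}

#' Full test-retest reliability report for one metric
#'
#' Runs the complete reproducibility battery on paired test/retest values:
#' paired t-test with Cohen's d and band, typical error, CV%, ICC (both
#' single-measurement forms), SEM and MDC. The internal identities
#' `SEM = SD * sqrt(1 - ICC)` and `MDC = SEM * 1.96 * sqrt(2)` hold
#' exactly by construction.
#'
#' @inheritParams typical_error
#' @param metric label for the measurement (e.g. `"cs_m_per_s"`).
#' @param icc_form which ICC enters SEM/MDC: `"ICC2_1"` (default) or
#'   `"ICC3_1"`; both are always reported.
#' @param cv_method passed to [cv_percent()].
#' @param sd_method SD entering the SEM: `"pooled"` over both sessions
#'   (default) or `"baseline"` (first session only).
#' @param d_method passed to [paired_effect()].
#' @return A list of class `"reliability_report"` with fields `metric`,
#'   `n`, `mean_test`, `mean_retest`, `mean_diff`, `p_value`,
#'   `effect_size_d`, `effect_band`, `te`, `cv_percent`, `icc`,
#'   `icc_form`, `icc2_1`, `icc3_1`, `sd_used`, `sem`, `mdc`.
#' @export
reliability_report <- function(test, retest, metric = "metric",
                               icc_form = c("ICC2_1", "ICC3_1"),
                               cv_method = c("ratio", "log"),
                               sd_method = c("pooled", "baseline"),
                               d_method = c("pooled", "dz")) {
  icc_form <- match.arg(icc_form)
  cv_method <- match.arg(cv_method)
  sd_method <- match.arg(sd_method)
  check_pairs(test, retest)
  pe <- paired_effect(test, retest, d_method = match.arg(d_method))
  icc2 <- suppressWarnings(icc(test, retest, "ICC2_1"))
  icc3 <- suppressWarnings(icc(test, retest, "ICC3_1"))
  icc_used <- if (icc_form == "ICC2_1") icc2 else icc3
  sd_used <- if (sd_method == "pooled") {
    sqrt((stats::var(test) + stats::var(retest)) / 2)
  } else {
    stats::sd(test)
  }
  sem_val <- if (is.finite(icc_used)) sem(sd_used, icc_used) else NA_real_
  out <- list(metric = metric, n = length(test),
              mean_test = mean(test), mean_retest = mean(retest),
              mean_diff = pe$mean_diff, p_value = pe$p_value,
              effect_size_d = pe$effect_size_d, effect_band = pe$effect_band,
              te = typical_error(test, retest),
              cv_percent = cv_percent(test, retest, cv_method),
              icc = icc_used, icc_form = icc_form,
              icc2_1 = icc2, icc3_1 = icc3,
              sd_used = sd_used,
              sem = sem_val,
              mdc = if (is.finite(sem_val)) mdc(sem_val) else NA_real_)
  class(out) <- "reliability_report"
  out
}

#' @export
print.reliability_report <- function(x, ...) {
  cat(sprintf("Test-retest reliability: %s (n = %d)\n", x$metric, x$n))
  cat(sprintf("  mean test %.4g, retest %.4g, diff %.4g (p = %.3g, d = %.3g [%s])\n",
              x$mean_test, x$mean_retest, x$mean_diff, x$p_value,
              x$effect_size_d, x$effect_band))
  cat(sprintf("  TE %.4g, CV %.3g%%, ICC(2,1) %.3g, ICC(3,1) %.3g, SEM %.4g, MDC %.4g\n",
              x$te, x$cv_percent, x$icc2_1, x$icc3_1, x$sem, x$mdc))
  invisible(x)
}
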