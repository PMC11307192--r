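#' Fit the critical-speed model (distance on time)
#'
#' Ordinary least squares of distance (m) on effort duration (s) across
#' maximal efforts. The slope is the critical speed CS (m/s), the boundary
#' between the heavy and severe exercise-intensity domains; the intercept
#' D' (m) is the finite distance reserve usable above CS.
#'
#' @param distance_m effort distances in metres (>= 2 values, positive).
#' @param time_s effort durations in seconds (>= 2 distinct values).
#' @return A list of class `"critical_fit"` with fields `variant = "speed"`,
#'   `slope` (CS, m/s), `slope_m_per_min`, `intercept` (D', m),
#'   `r_squared`, `n_points`, `residuals`, `se_slope`.
#' @examples
#' fit_critical_speed(c(400, 800, 1200), c(250, 500, 750))  # CS 1.6, D' 0
#' @export
fit_critical_speed <- function(distance_m, time_s) {
  check_fit_input(distance_m, time_s)
  fit <- stats::lm(distance_m ~ time_s)
  new_critical_fit("speed", fit, x = time_s, y = distance_m)
}

#' Fit the critical-heart-rate model (heartbeats on time)
#'
#' Ordinary least squares of total heartbeats (beats) on effort duration in
#' minutes. The slope is the critical heart rate CHR (beats/min), the
#' internal-load analogue of critical speed; the intercept HB' (beats) is
#' the heartbeat analogue of the distance reserve D'.
#'
#' @param hb_beats total heartbeats per effort (non-negative).
#' @param time_s effort durations in seconds (>= 2 distinct values).
#' @return A `"critical_fit"` with `variant = "hr"`, `slope` (CHR,
#'   beats/min) and `intercept` (HB', beats).
#' @examples
#' fit_critical_hr(c(670, 1320, 2100), c(300, 600, 960))  # CHR 130, HB' 20
#' @export
fit_critical_hr <- function(hb_beats, time_s) {
  check_fit_input(hb_beats, time_s, yname = "hb_beats")
  if (any(hb_beats < 0)) stop("hb_beats must be non-negative", call. = FALSE)
  time_min <- time_s / 60
  fit <- stats::lm(hb_beats ~ time_min)
  new_critical_fit("hr", fit, x = time_min, y = hb_beats)
}

#' Fit the inverse-time form of the critical-speed model
#'
#' Regresses mean speed (d/t) on inverse time (1/t):
#' `speed = D' * (1/t) + CS`. On noiseless collinear data this recovers
#' exactly the same CS and D' as the distance-time fit; on noisy data the
#' two parameterizations weight errors differently and generally disagree.
#' Both are reported so the sensitivity of the estimates to the chosen
#' parameterization can be inspected; no reconciliation is attempted.
#'
#' @inheritParams fit_critical_speed
#' @return A `"critical_fit"` with `variant = "speed_inverse_time"`;
#'   `slope` holds CS (the regression intercept) and `intercept` holds D'
#'   (the regression slope on 1/t), so fields compare directly with
#'   [fit_critical_speed()].
#' @export
fit_inverse_time_form <- function(distance_m, time_s) {
  check_fit_input(distance_m, time_s)
  speed <- distance_m / time_s
  inv_t <- 1 / time_s
  fit <- stats::lm(speed ~ inv_t)
  cf <- stats::coef(fit)
  sm <- suppressWarnings(summary(fit))  # collinear input is a designed case
  structure(list(variant = "speed_inverse_time",
                 slope = unname(cf[1]),                 # CS, m/s
                 slope_m_per_min = unname(cf[1]) * 60,
                 intercept = unname(cf[2]),             # D', m
                 r_squared = r_squared_of(fit, speed),
                 n_points = length(speed),
                 residuals = unname(stats::residuals(fit)),
                 se_slope = unname(sm$coefficients[1, 2])),
            class = "critical_fit")
}

check_fit_input <- function(y, time_s, yname = "distance_m") {
  if (length(y) != length(time_s))
    stop(sprintf("%s and time_s must have the same length", yname), call. = FALSE)
  if (length(time_s) < 2L)
    stop("at least 2 efforts are required to fit a two-parameter model", call. = FALSE)
  if (length(time_s) == 2L)
    warning("only 2 efforts supplied; the protocol prescribes 3 distances and the fit has no residual degrees of freedom",
            call. = FALSE)
  if (any(!is.finite(y)) || any(!is.finite(time_s)))
    stop("non-finite values in fit input", call. = FALSE)
  if (any(time_s <= 0)) stop("time_s must be positive", call. = FALSE)
  if (yname == "distance_m" && any(y <= 0))
    stop("distance_m must be positive", call. = FALSE)
  if (length(unique(time_s)) < 2L)
    stop("identical effort times: singular design, slope undefined", call. = FALSE)
  invisible(NULL)
}

r_squared_of <- function(fit, y) {
  tss <- sum((y - mean(y))^2)
  if (tss == 0) return(1)
  max(0, min(1, 1 - sum(stats::residuals(fit)^2) / tss))
}

new_critical_fit <- function(variant, fit, x, y) {
  cf <- stats::coef(fit)
  sm <- suppressWarnings(summary(fit))  # collinear input is a designed case
  slope <- unname(cf[2])
  structure(list(variant = variant,
                 slope = slope,
                 slope_m_per_min = if (variant == "speed") slope * 60 else NA_real_,
                 intercept = unname(cf[1]),
                 r_squared = r_squared_of(fit, y),
                 n_points = length(y),
                 residuals = unname(stats::residuals(fit)),
                 se_slope = unname(sm$coefficients[2, 2])),
            class = "critical_fit")
}

#' @export
print.critical_fit <- function(x, ...) {
  lab <- switch(x$variant,
                speed = sprintf("critical speed CS = %.4f m/s (%.2f m/min), D' = %.2f m",
                                x$slope, x$slope_m_per_min, x$intercept),
                speed_inverse_time = sprintf("inverse-time form: CS = %.4f m/s, D' = %.2f m",
                                             x$slope, x$intercept),
                hr = sprintf("critical heart rate CHR = %.2f beats/min, HB' = %.2f beats",
                             x$slope, x$intercept))
  cat(sprintf("Critical-power fit (%s): %s; R^2 = %.4f, n = %d\n",
              x$variant, lab, x$r_squared, x$n_points))
  invisible(x)
}

#' Predict the time to cover a distance from a critical-speed fit
#'
#' Inverts the fitted distance-time line: `t = (d - D') / CS`.
#'
#' @param fit a `"critical_fit"` with `variant = "speed"` (or the
#'   inverse-time form).
#' @param distance_m target distance in metres; must exceed D'.
#' @return predicted time in seconds, strictly increasing in distance.
#' @export
predict_time <- function(fit, distance_m) {
  if (!inherits(fit, "critical_fit") || !fit$variant %in% c("speed", "speed_inverse_time"))
    stop("fit must be a speed-variant critical_fit", call. = FALSE)
  if (fit$slope <= 0) stop("fitted critical speed is not positive; cannot invert", call. = FALSE)
  if (any(distance_m <= fit$intercept))
    stop(sprintf("distance (%g m) must exceed the distance reserve D' (%g m)",
                 min(distance_m), fit$intercept), call. = FALSE)
  (distance_m - fit$intercept) / fit$slope
}

#' Classify a target heart rate against the critical heart rate
#'
#' Training above the CHR places the session in the severe intensity
#' domain; a band of +/- `tolerance_bpm` around the CHR is reported as "at"
#' the critical intensity.
#'
#' @param fit a `"critical_fit"` with `variant = "hr"`, or a single CHR
#'   value in beats/min.
#' @param target_hr_bpm target heart rate in beats/min.
#' @param tolerance_bpm half-width of the "at CHR" band (default 3).
#' @return list with `chr_bpm`, `target_hr_bpm`, `zone` (one of
#'   `"below_chr"`, `"at_chr"`, `"above_chr"`) and `guidance`.
#' @export
prescribe_intensity <- function(fit, target_hr_bpm, tolerance_bpm = 3) {
  chr <- if (inherits(fit, "critical_fit")) {
    if (fit$variant != "hr")
      stop("intensity prescription needs an hr-variant critical_fit", call. = FALSE)
    fit$slope
  } else {
    stop_if_not_number(fit, "fit (CHR)", positive = TRUE)
  }
  stop_if_not_number(target_hr_bpm, "target_hr_bpm", positive = TRUE)
  stop_if_not_number(tolerance_bpm, "tolerance_bpm", nonneg = TRUE)
  zone <- if (abs(target_hr_bpm - chr) <= tolerance_bpm) "at_chr"
          else if (target_hr_bpm > chr) "above_chr" else "below_chr"
  guidance <- switch(zone,
    below_chr = "heavy domain or below: sustainable continuously for long durations",
    at_chr = "at the critical heart rate: sustainable continuously for roughly 30-60 min",
    above_chr = "severe domain: tolerable only for limited durations or intermittently")
  list(chr_bpm = chr, target_hr_bpm = target_hr_bpm, zone = zone,
       guidance = guidance)
}

.hrmax_formulas <- list(
  "220-age"     = function(age) 220 - age,
  "208-0.7age"  = function(age) 208 - 0.7 * age,
  "207-0.7age"  = function(age) 207 - 0.7 * age
)

#' Critical heart rate as a percentage of age-predicted maximal HR
#'
#' @param chr_bpm critical heart rate in beats/min.
#' @param age_years age in years, in [18, 100].
#' @param formula age-predicted HRmax equation: `"208-0.7age"` (default),
#'   `"220-age"`, or `"207-0.7age"`.
#' @return percentage of predicted maximal heart rate.
#' @examples
#' relative_intensity(104, 60, "220-age")  # 65
#' @export
relative_intensity <- function(chr_bpm, age_years, formula = "208-0.7age") {
  stop_if_not_number(chr_bpm, "chr_bpm", positive = TRUE)
  if (!is.numeric(age_years) || any(age_years < 18 | age_years > 100))
    stop("age_years must lie in [18, 100]", call. = FALSE)
  if (!formula %in% names(.hrmax_formulas))
    stop(sprintf("unknown HRmax formula '%s'; choose one of: %s", formula,
                 paste(names(.hrmax_formulas), collapse = ", ")), call. = FALSE)
  100 * chr_bpm / .hrmax_formulas[[formula]](age_years)
}
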