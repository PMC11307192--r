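#' Construct a heart-rate series
#'
#' A heart-rate series holds the samples recorded during one walking effort.
#' Each sample is the average heart rate over one recording window (5 s by
#' default for chest-strap monitors exporting 5-s averages); the timestamp
#' marks the *end* of the averaging window, in seconds from effort start.
#'
#' @param elapsed_s numeric vector of sample times in seconds from effort
#'   start; must be non-negative and strictly increasing.
#' @param hr_bpm numeric vector of heart rates in beats per minute, same
#'   length as `elapsed_s`. Values outside the physiologic range (20, 250)
#'   are kept but flagged.
#' @param interval_s nominal sampling interval in seconds (default 5).
#' @return A data frame of class `"hr_series"` with columns `elapsed_s`,
#'   `hr_bpm` and logical `flagged`, and attribute `interval_s`. Gaps larger
#'   than the nominal interval are reported as a message, never imputed.
#' @examples
#' hr_series(c(5, 10, 15), c(95, 110, 120))
#' @export
hr_series <- function(elapsed_s, hr_bpm, interval_s = 5) {
  if (length(elapsed_s) != length(hr_bpm))
    stop("elapsed_s and hr_bpm must have the same length", call. = FALSE)
  if (length(elapsed_s) < 1L)
    stop("a heart-rate series needs at least one sample", call. = FALSE)
  if (!is.numeric(elapsed_s) || !is.numeric(hr_bpm))
    stop("elapsed_s and hr_bpm must be numeric", call. = FALSE)
  if (anyNA(elapsed_s) || anyNA(hr_bpm))
    stop("heart-rate series may not contain missing values", call. = FALSE)
  if (any(elapsed_s < 0))
    stop("elapsed_s must be non-negative", call. = FALSE)
  if (length(elapsed_s) > 1L && any(diff(elapsed_s) <= 0))
    stop("elapsed_s must be strictly increasing", call. = FALSE)
  stop_if_not_number(interval_s, "interval_s", positive = TRUE)
  flagged <- hr_bpm <= 20 | hr_bpm >= 250
  if (any(flagged))
    warning(sprintf("%d sample(s) outside the physiologic HR range (20, 250) were flagged",
                    sum(flagged)), call. = FALSE)
  gaps <- diff(elapsed_s)
  if (length(gaps) && any(gaps > interval_s + 1e-9))
    message(sprintf("hr_series: %d gap(s) larger than the %g-s sampling interval (max %g s); no imputation applied",
                    sum(gaps > interval_s + 1e-9), interval_s, max(gaps)))
  out <- data.frame(elapsed_s = as.numeric(elapsed_s),
                    hr_bpm = as.numeric(hr_bpm),
                    flagged = flagged)
  attr(out, "interval_s") <- interval_s
  class(out) <- c("hr_series", "data.frame")
  out
}

#' Read a heart-rate series from a CSV file
#'
#' Reads a two-column CSV (elapsed seconds, heart rate in beats per minute)
#' as exported from a heart-rate monitor. A header row is detected
#' automatically; column names are configurable for files using a different
#' dialect.
#'
#' @param path path to a CSV file.
#' @param time_col,hr_col column names used when the file has a header
#'   (defaults `"elapsed_s"` and `"hr_bpm"`). Ignored for headerless files,
#'   where the first column is time and the second heart rate.
#' @param interval_s nominal sampling interval in seconds (default 5).
#' @param sep field separator (default `","`).
#' @return an [hr_series] object.
#' @export
read_hr_series <- function(path, time_col = "elapsed_s", hr_col = "hr_bpm",
                           interval_s = 5, sep = ",") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  first <- readLines(path, n = 1L)
  if (!length(first)) stop(sprintf("empty HR file: %s", path), call. = FALSE)
  fields <- strsplit(first, sep, fixed = TRUE)[[1]]
  has_header <- any(is.na(suppressWarnings(as.numeric(fields))))
  raw <- utils::read.table(path, header = has_header, sep = sep,
                           stringsAsFactors = FALSE)
  if (has_header) {
    missing <- setdiff(c(time_col, hr_col), names(raw))
    if (length(missing))
      stop(sprintf("HR file %s is missing column(s): %s", path,
                   paste(missing, collapse = ", ")), call. = FALSE)
    tvec <- raw[[time_col]]
    hvec <- raw[[hr_col]]
  } else {
    if (ncol(raw) < 2L)
      stop(sprintf("HR file %s must have two columns (time, HR)", path), call. = FALSE)
    tvec <- raw[[1]]
    hvec <- raw[[2]]
  }
  for (v in list(time = tvec, hr = hvec)) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(v))))
    if (length(bad))
      stop(sprintf("non-numeric value in %s at data row %d", path, bad[1]),
           call. = FALSE)
  }
  hr_series(as.numeric(tvec), as.numeric(hvec), interval_s = interval_s)
}

#' Construct an effort trial
#'
#' One timed walking effort: a fixed distance covered as fast as possible
#' (no running) with the stopwatch time and the heart-rate recording.
#'
#' @param participant_id participant identifier (coerced to character).
#' @param session one of `"test"`, `"retest"`, `"pre"`, `"post"`.
#' @param distance_m effort distance in metres (> 0); the protocol uses
#'   400, 800 and 1200 m but other distances are accepted.
#' @param time_s stopwatch time in seconds (0.01-s resolution, > 0).
#' @param samples an [hr_series] recorded during the effort. The last
#'   sample may run at most one sampling interval past `time_s`.
#' @return A list of class `"effort_trial"`.
#' @export
effort_trial <- function(participant_id, session, distance_m, time_s, samples) {
  session <- match.arg(session, c("test", "retest", "pre", "post"))
  stop_if_not_number(distance_m, "distance_m", positive = TRUE)
  stop_if_not_number(time_s, "time_s", positive = TRUE)
  if (!inherits(samples, "hr_series"))
    stop("samples must be an hr_series", call. = FALSE)
  interval <- attr(samples, "interval_s")
  last <- samples$elapsed_s[nrow(samples)]
  if (last > time_s + interval + 1e-9)
    stop(sprintf("last HR sample (%g s) runs more than one interval past the stopwatch time (%g s)",
                 last, time_s), call. = FALSE)
  structure(list(participant_id = as.character(participant_id),
                 session = session,
                 distance_m = distance_m,
                 time_s = time_s,
                 samples = samples),
            class = "effort_trial")
}

#' @export
print.effort_trial <- function(x, ...) {
  cat(sprintf("Effort trial: participant %s, %s session, %g m in %.2f s (%d HR samples)\n",
              x$participant_id, x$session, x$distance_m, x$time_s, nrow(x$samples)))
  invisible(x)
}

.cohort_columns <- c("id", "sex", "age_years", "height_m", "mass_kg",
                     "updrs2", "updrs3", "hy", "mmse",
                     "tmt_a_s", "tmt_b_s", "tug_s", "in_experiment2")
.cohort_numeric <- setdiff(.cohort_columns, c("id", "sex", "in_experiment2"))

validate_cohort <- function(df) {
  unknown <- setdiff(names(df), .cohort_columns)
  if (length(unknown))
    stop(sprintf("unknown cohort column(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  missing <- setdiff(.cohort_columns, names(df))
  if (length(missing))
    stop(sprintf("missing cohort column(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  for (col in .cohort_numeric) {
    v <- df[[col]]
    if (!is.numeric(v)) stop(sprintf("column %s must be numeric", col), call. = FALSE)
    if (any(v < 0, na.rm = TRUE))
      stop(sprintf("column %s has negative values", col), call. = FALSE)
  }
  hy <- df$hy
  if (any(hy < 1 | hy > 5 | abs(hy * 2 - round(hy * 2)) > 1e-9, na.rm = TRUE))
    stop("hy must lie in [1, 5] in steps of 0.5", call. = FALSE)
  df$in_experiment2 <- as.logical(df$in_experiment2)
  class(df) <- c("cohort", "data.frame")
  df
}

#' Read a cohort characteristics table
#'
#' Reads the participant characteristics table (age, anthropometrics,
#' clinical scores, and the flag marking which participants entered the
#' training experiment) from a TSV or CSV file and validates its schema.
#'
#' @param path path to the table; tab-separated unless the extension is
#'   `.csv`.
#' @return A validated data frame of class `"cohort"` with columns
#'   `id, sex, age_years, height_m, mass_kg, updrs2, updrs3, hy, mmse,
#'   tmt_a_s, tmt_b_s, tug_s, in_experiment2`.
#' @export
read_cohort_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  if (file.size(path) == 0 || !length(readLines(path, n = 1L))) {
    warning("empty cohort table", call. = FALSE)
    empty <- as.data.frame(setNames(rep(list(logical(0)), length(.cohort_columns)),
                                    .cohort_columns))
    class(empty) <- c("cohort", "data.frame")
    return(empty)
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  validate_cohort(df)
}

# flatten a (possibly nested) report list to a named numeric/character vector
# with dotted keys, for TSV output
flatten_report <- function(x, prefix = "") {
  out <- list()
  for (nm in names(x)) {
    key <- if (nzchar(prefix)) paste(prefix, nm, sep = ".") else nm
    v <- x[[nm]]
    if (is.list(v)) {
      out <- c(out, flatten_report(v, key))
    } else if (length(v) > 1L) {
      for (i in seq_along(v)) out[[paste(key, i, sep = ".")]] <- v[[i]]
    } else {
      out[[key]] <- v
    }
  }
  out
}

#' Write an analysis report to disk
#'
#' Serializes a report object (a reliability report, a critical fit, or any
#' named list of results) to JSON or to a two-column key/value TSV. Nested
#' lists are flattened to dotted keys in the TSV form. Values round-trip
#' through [read_report()] to within 1e-9.
#'
#' @param report a named list (or object built on one).
#' @param path output path.
#' @param format `"json"` or `"tsv"`.
#' @export
write_report <- function(report, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  rep_list <- unclass(report)
  rep_list$samples <- NULL  # raw series are data, not report content
  if (format == "json") {
    jsonlite::write_json(rep_list, path, auto_unbox = TRUE, digits = NA,
                         null = "null", na = "null")
  } else {
    flat <- flatten_report(rep_list)
    df <- data.frame(key = names(flat),
                     value = vapply(flat, function(v) {
                       if (is.numeric(v)) sprintf("%.12g", v) else as.character(v)
                     }, character(1)),
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(NULL)
}

#' Read back a report written by [write_report()]
#'
#' @param path path to a JSON or TSV report.
#' @param format `"json"` or `"tsv"`; inferred from the extension when missing.
#' @return a named list (JSON) or a named vector with dotted keys (TSV);
#'   numeric-looking TSV values are converted back to numbers.
#' @export
read_report <- function(path, format = NULL) {
  if (is.null(format))
    format <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "tsv" else "json"
  if (format == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE, colClasses = "character")
    vals <- lapply(df$value, function(v) {
      num <- suppressWarnings(as.numeric(v))
      if (!is.na(num)) num else v
    })
    stats::setNames(vals, df$key)
  }
}
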