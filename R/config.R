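#' Study configuration
#'
#' Bundles the protocol parameters that drive every stage of the compliance
#' pipeline: the accelerometer sampling rate and the completeness fraction
#' an hour of streaming must reach to count, the waking window used by the
#' monitoring rule, the study length, the burn-in day from which
#' longitudinal change is quantified, the smoothing window, and the
#' weighted-score parameters of the twice-weekly monitoring algorithm.
#'
#' Defaults reflect a six-month protocol with a 50 Hz wrist accelerometer:
#' an hour of streaming is valid when at least 90% of the expected records
#' arrive, a compliant day streams through at least 90% of the 09:00-21:00
#' waking window, and the monitoring score weights the last three days
#' 4/2/1 with a flag threshold of 3 points.
#'
#' @param sampling_rate_hz Accelerometer sampling rate in Hz.
#' @param valid_hour_fraction Fraction of expected records (and of the
#'   waking window) required for validity, in (0, 1].
#' @param waking_window Integer vector of length 2, start and end clock hour
#'   of the waking window (half-open, so \code{c(9, 21)} spans 09:00-21:00).
#' @param study_length_days Protocol study length in days.
#' @param burn_in_day Study day from which longitudinal change is measured.
#' @param smoothing_window_days Width of the trailing moving average.
#' @param score_weights Monitoring score weights for 1, 2 and 3 days before
#'   the query date.
#' @param score_threshold Minimum score; below it the streaming flag raises.
#' @param assessment_lookback_days Trailing window for the home-assessment
#'   monitoring criterion.
#' @param assessment_min_count Minimum assessment performances required in
#'   the lookback window.
#' @param assessment_session_minutes Events from one patient within this
#'   many minutes are grouped into a single assessment performance.
#' @return An object of class \code{study_config} (a named list).
#' @examples
#' cfg <- study_config()
#' cfg$score_weights
#' @export
study_config <- function(sampling_rate_hz = 50,
                         valid_hour_fraction = 0.9,
                         waking_window = c(9L, 21L),
                         study_length_days = 182L,
                         burn_in_day = 14L,
                         smoothing_window_days = 7L,
                         score_weights = c(4, 2, 1),
                         score_threshold = 3,
                         assessment_lookback_days = 8L,
                         assessment_min_count = 3L,
                         assessment_session_minutes = 30) {
  cfg <- list(
    sampling_rate_hz = as.numeric(sampling_rate_hz),
    valid_hour_fraction = as.numeric(valid_hour_fraction),
    waking_window = as.integer(waking_window),
    study_length_days = as.integer(study_length_days),
    burn_in_day = as.integer(burn_in_day),
    smoothing_window_days = as.integer(smoothing_window_days),
    score_weights = as.numeric(score_weights),
    score_threshold = as.numeric(score_threshold),
    assessment_lookback_days = as.integer(assessment_lookback_days),
    assessment_min_count = as.integer(assessment_min_count),
    assessment_session_minutes = as.numeric(assessment_session_minutes)
  )
  class(cfg) <- "study_config"
  validate_study_config(cfg)
  cfg
}

validate_study_config <- function(cfg) {
  stopifnot(inherits(cfg, "study_config"))
  num_pos <- c("sampling_rate_hz", "valid_hour_fraction", "study_length_days",
               "burn_in_day", "smoothing_window_days", "score_threshold",
               "assessment_lookback_days", "assessment_min_count",
               "assessment_session_minutes")
  for (f in num_pos) {
    v <- cfg[[f]]
    if (length(v) != 1L || !is.finite(v) || v <= 0)
      stop("study_config field '", f, "' must be a single positive number",
           call. = FALSE)
  }
  if (cfg$valid_hour_fraction > 1)
    stop("valid_hour_fraction must lie in (0, 1]", call. = FALSE)
  if (length(cfg$waking_window) != 2L ||
      cfg$waking_window[1] < 0 || cfg$waking_window[2] > 24 ||
      cfg$waking_window[1] >= cfg$waking_window[2])
    stop("waking_window must be two clock hours with start < end", call. = FALSE)
  if (length(cfg$score_weights) != 3L || any(cfg$score_weights < 0))
    stop("score_weights must be three nonnegative numbers", call. = FALSE)
  invisible(cfg)
}

#' @export
print.study_config <- function(x, ...) {
  cat("Study configuration\n")
  cat(sprintf("  sampling rate:        %g Hz\n", x$sampling_rate_hz))
  cat(sprintf("  valid-hour fraction:  %g\n", x$valid_hour_fraction))
  cat(sprintf("  waking window:        %02d:00-%02d:00\n",
              x$waking_window[1], x$waking_window[2]))
  cat(sprintf("  study length:         %d days (burn-in day %d)\n",
              x$study_length_days, x$burn_in_day))
  cat(sprintf("  smoothing window:     %d days\n", x$smoothing_window_days))
  cat(sprintf("  score weights:        %s (threshold %g)\n",
              paste(x$score_weights, collapse = "/"), x$score_threshold))
  cat(sprintf("  assessment criterion: >= %d in %d days\n",
              x$assessment_min_count, x$assessment_lookback_days))
  invisible(x)
}

#' Read or write a study configuration file
#'
#' The on-disk format is a flat \code{key = value} text file (one field per
#' line, \code{#} comments allowed). Vector fields are comma-separated.
#'
#' @param path Path to the configuration file.
#' @return \code{read_study_config} returns a \code{study_config};
#'   \code{write_study_config} returns \code{path} invisibly.
#' @export
read_study_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*=\\s*(.*)$", lines))
  bad <- lines[vapply(kv, length, 1L) != 3L]
  if (length(bad))
    stop("unparsable config line(s): ", paste(bad, collapse = "; "), call. = FALSE)
  vals <- lapply(kv, function(m) {
    v <- strsplit(m[3], ",")[[1]]
    as.numeric(trimws(gsub('"', "", v)))
  })
  names(vals) <- vapply(kv, `[`, "", 2L)
  known <- names(formals(study_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  do.call(study_config, vals)
}

#' @rdname read_study_config
#' @param config A \code{study_config} object.
#' @export
write_study_config <- function(config, path) {
  validate_study_config(config)
  lines <- vapply(names(unclass(config)), function(f) {
    sprintf("%s = %s", f, paste(config[[f]], collapse = ", "))
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Length of the waking window in hours
#' @param config A \code{study_config}.
#' @return Number of hours between the window's start and end.
#' @keywords internal
waking_window_hours <- function(config) {
  diff(config$waking_window)
}
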