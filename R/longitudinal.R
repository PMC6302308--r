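#' @title Longitudinal cohort aggregation
#' @description Cohort-level compliance curves: per study-day cross-patient
#'   means with dropout censoring, a trailing seven-day moving average, and
#'   the percent-change summary from the burn-in day to the final study
#'   day.
#' @name longitudinal
NULL

#' Censored cohort mean of one metric by study day
#'
#' Averages a metric across the patients active on each study day.
#' Patients are censored from their dropout date onward: they leave both
#' the numerator and the denominator, so \code{n_active} records how many
#' patients remain.
#'
#' @param daily A \code{daily_metrics} (or \code{daily_streaming}) table,
#'   zero-filled over active patient-days.
#' @param roster A validated roster (used for reporting only; activity is
#'   already encoded in the zero-filled rows).
#' @param metric Name of the metric column to aggregate.
#' @param config A \code{study_config}; the smoothing window width.
#' @return Data frame of class \code{cohort_series} with columns
#'   \code{study_day, metric, mean_value, n_active, smoothed_value}.
#' @export
cohort_mean <- function(daily, roster, metric, config = study_config()) {
  valid <- setdiff(names(daily), c("patient_id", "study_day", "date"))
  if (!metric %in% valid)
    stop("unknown metric '", metric, "'; available: ",
         paste(valid, collapse = ", "), call. = FALSE)
  agg <- stats::aggregate(daily[[metric]],
                          by = list(study_day = daily$study_day),
                          FUN = function(v) c(mean = mean(v), n = length(v)))
  out <- data.frame(study_day = agg$study_day,
                    metric = metric,
                    mean_value = agg$x[, "mean"],
                    n_active = as.integer(agg$x[, "n"]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$study_day), , drop = FALSE]
  rownames(out) <- NULL
  out <- smooth_series(out, config$smoothing_window_days)
  class(out) <- unique(c("cohort_series", class(out)))
  out
}

#' Trailing moving average of a cohort series
#'
#' Smooths \code{mean_value} with a trailing window covering the current
#' day and the \code{window_days - 1} preceding days; at the start of the
#' series the window shortens to the days available, so the smoother never
#' looks ahead and a constant series is a fixed point.
#'
#' @param series A cohort series (any frame with \code{mean_value} ordered
#'   by \code{study_day}).
#' @param window_days Window width in days, at least 1.
#' @return The series with a \code{smoothed_value} column.
#' @export
smooth_series <- function(series, window_days = 7L) {
  stopifnot(window_days >= 1L)
  x <- series$mean_value
  n <- length(x)
  cs <- cumsum(x)
  lo <- pmax(seq_len(n) - window_days, 0L)
  series$smoothed_value <- (cs - c(0, cs)[lo + 1L]) / (seq_len(n) - lo)
  series
}

#' Percent change between two values, decline positive
#'
#' @param start_value Value at the start (e.g. the burn-in day).
#' @param end_value Value at the end of the study.
#' @return \code{100 * (start_value - end_value) / start_value}; positive
#'   for a decline, negative for an increase.
#' @examples
#' percent_change(5.82, 3.83)  # 34.2% decline
#' percent_change(0.72, 0.73)  # -1.39%: a slight increase
#' @export
percent_change <- function(start_value, end_value) {
  if (any(start_value == 0))
    stop("percent change undefined for start_value 0", call. = FALSE)
  100 * (start_value - end_value) / start_value
}

#' Burn-in-to-end change summary of a smoothed cohort series
#'
#' Early-enrollment behaviour is unstable, so longitudinal change is
#' quantified from the burn-in day (default study day 14) to the last
#' study day with any active patient (capped at the protocol length). The
#' study mean averages the smoothed values over that same span.
#'
#' @param series A \code{cohort_series} with smoothed values, covering the
#'   burn-in day.
#' @param config A \code{study_config}.
#' @return One-row data frame \code{metric, start_day, end_day,
#'   start_value, end_value, percent_change, study_mean}.
#' @export
percent_change_summary <- function(series, config = study_config()) {
  active <- series[series$n_active > 0 &
                     series$study_day <= config$study_length_days, ,
                   drop = FALSE]
  start_day <- config$burn_in_day
  if (!start_day %in% active$study_day)
    stop("series does not cover burn-in day ", start_day, call. = FALSE)
  end_day <- max(active$study_day)
  start_value <- active$smoothed_value[active$study_day == start_day]
  end_value <- active$smoothed_value[active$study_day == end_day]
  span <- active[active$study_day >= start_day, , drop = FALSE]
  data.frame(metric = series$metric[1],
             start_day = start_day,
             end_day = end_day,
             start_value = start_value,
             end_value = end_value,
             percent_change = percent_change(start_value, end_value),
             study_mean = mean(span$smoothed_value),
             stringsAsFactors = FALSE)
}

#' Cohort series and change summaries for every metric
#'
#' @param daily A \code{daily_metrics} table.
#' @param roster A validated roster.
#' @param config A \code{study_config}.
#' @param metrics Metric columns to aggregate; defaults to the metrics the
#'   study collected.
#' @return List with \code{series} (stacked \code{cohort_series}) and
#'   \code{changes} (one \code{percent_change_summary} row per metric).
#' @export
longitudinal_summary <- function(daily, roster, config = study_config(),
                                 metrics = metric_names(daily)) {
  series <- lapply(metrics, function(m) cohort_mean(daily, roster, m, config))
  changes <- do.call(rbind, lapply(series, percent_change_summary,
                                   config = config))
  series <- do.call(rbind, series)
  rownames(series) <- rownames(changes) <- NULL
  list(series = series, changes = changes)
}
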