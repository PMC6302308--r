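#' @title Twice-weekly compliance monitoring
#' @description The intervention-monitoring rule used during the trial:
#'   a day is compliant when streaming covers at least 90\% of the
#'   09:00-21:00 waking window; the last three calendar days are scored
#'   4/2/1 points (yesterday / two / three days ago) and a score below 3
#'   raises the streaming flag. Independently, fewer than three
#'   home-assessment performances over the trailing eight days raises the
#'   assessment flag. Either flag recommends contacting the patient.
#' @name monitoring
NULL

#' Is a day streaming-compliant?
#'
#' @param waking_streaming_hours Valid streaming hours inside the waking
#'   window for the day (vectorized).
#' @param config A \code{study_config}.
#' @return Logical; \code{TRUE} when the hours reach
#'   \code{valid_hour_fraction} of the waking-window length (default
#'   0.9 x 12 = 10.8 h, boundary inclusive).
#' @examples
#' is_compliant_day(10.8)   # TRUE (boundary)
#' is_compliant_day(10.79)  # FALSE
#' @export
is_compliant_day <- function(waking_streaming_hours, config = study_config()) {
  waking_streaming_hours >=
    config$valid_hour_fraction * waking_window_hours(config)
}

#' Weighted three-day streaming score
#'
#' @param flags Logical vector of length 3: compliance of the day 1, 2 and
#'   3 days before the query date (in that order).
#' @param config A \code{study_config} providing the weights (default
#'   4/2/1).
#' @return Integer score in 0..7 under the default weights; three
#'   non-compliant days score 0.
#' @examples
#' streaming_score(c(TRUE, TRUE, TRUE))    # 7
#' streaming_score(c(TRUE, FALSE, FALSE))  # 4
#' @export
streaming_score <- function(flags, config = study_config()) {
  stopifnot(length(flags) == 3L, is.logical(flags))
  sum(config$score_weights[which(flags)])
}

#' Default twice-weekly monitoring schedule
#'
#' The protocol monitors compliance twice a week; the concrete weekdays are
#' configurable and default to Monday and Thursday.
#'
#' @param from,to Date range to cover.
#' @param weekdays_wanted Weekday names of the monitoring days.
#' @return Vector of query dates.
#' @export
monitoring_schedule <- function(from, to,
                                weekdays_wanted = c("Monday", "Thursday")) {
  dates <- seq(as.Date(from), as.Date(to), by = "day")
  dates[weekdays(dates) %in% weekdays_wanted]
}

#' Run the monitoring algorithm over a query schedule
#'
#' For each patient and scheduled query date inside the patient's active
#' period, computes the three-day weighted streaming score and the
#' trailing eight-day assessment count, and raises the corresponding
#' flags. Days before enrollment (or otherwise absent from the streaming
#' table) count as non-compliant, so early-study queries score
#' conservatively over the days available.
#'
#' @param daily_str Output of \code{\link{daily_streaming}} (needs
#'   \code{waking_streaming_hours}).
#' @param events Compliance events (assessment events are session-grouped
#'   internally); ignored when the study has no assessment component.
#' @param roster A validated roster.
#' @param config A \code{study_config}.
#' @param schedule Query dates; defaults to Mondays and Thursdays across
#'   the roster's active span.
#' @param include_assessments Whether the study has the home-assessment
#'   criterion (default: only if assessment events exist).
#' @return Data frame \code{patient_id, query_date, score, streaming_flag,
#'   assessment_count_8d, assessment_flag, contact_recommended}.
#' @export
run_monitoring <- function(daily_str, events, roster,
                           config = study_config(), schedule = NULL,
                           include_assessments = NULL) {
  roster <- validate_roster(roster)
  grid <- patient_days(roster, config)
  if (is.null(schedule))
    schedule <- monitoring_schedule(min(grid$date), max(grid$date))
  if (is.null(include_assessments))
    include_assessments <- any(events$event_kind == "assessment")
  compliant <- daily_str
  compliant$ok <- is_compliant_day(daily_str$waking_streaming_hours, config)
  ses <- assessment_sessions(events, config)
  pieces <- lapply(seq_len(nrow(roster)), function(i) {
    pid <- roster$patient_id[i]
    pdays <- grid$date[grid$patient_id == pid]
    q <- schedule[schedule >= min(pdays) & schedule <= max(pdays)]
    if (!length(q)) return(NULL)
    ok_dates <- compliant$date[compliant$patient_id == pid & compliant$ok]
    ses_dates <- ses$date[ses$patient_id == pid]
    score <- vapply(q, function(d) {
      flags <- (d - 1:3) %in% ok_dates
      streaming_score(flags, config)
    }, numeric(1))
    a8 <- vapply(q, function(d) {
      sum(ses_dates > d - config$assessment_lookback_days & ses_dates <= d)
    }, numeric(1))
    data.frame(patient_id = pid, query_date = q, score = score,
               streaming_flag = score < config$score_threshold,
               assessment_count_8d = as.integer(a8),
               assessment_flag = include_assessments &
                 a8 < config$assessment_min_count,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  if (is.null(out))
    out <- data.frame(patient_id = character(0),
                      query_date = as.Date(character(0)), score = numeric(0),
                      streaming_flag = logical(0),
                      assessment_count_8d = integer(0),
                      assessment_flag = logical(0))
  out$contact_recommended <- out$streaming_flag | out$assessment_flag
  rownames(out) <- NULL
  out
}
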