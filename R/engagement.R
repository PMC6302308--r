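#' @title App-engagement compliance metrics
#' @description Daily counts of the three app-based metrics: medication
#'   reports (both \code{take} and \code{skip} count), symptom-report
#'   events (one event per app interaction regardless of how many symptoms
#'   it lists), and structured home-assessment performances (the task
#'   events of one sitting grouped into a single performance).
#' @name engagement_metrics
NULL

# Zero-filled per-day event counts over the active patient-day grid.
daily_event_counts <- function(events, roster, config, value_name) {
  grid <- patient_days(roster, config)
  if (nrow(events)) {
    unknown <- setdiff(unique(events$patient_id), roster$patient_id)
    if (length(unknown))
      stop("events for patients absent from roster: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    ev <- data.frame(patient_id = events$patient_id,
                     date = as.Date(events$timestamp, tz = "UTC"))
    agg <- stats::aggregate(list(n = rep(1L, nrow(ev))),
                            by = list(patient_id = ev$patient_id,
                                      date = ev$date), FUN = sum)
  } else {
    agg <- data.frame(patient_id = character(0), date = as.Date(character(0)),
                      n = integer(0))
  }
  out <- merge(grid, agg, by = c("patient_id", "date"), all.x = TRUE)
  out$n[is.na(out$n)] <- 0L
  names(out)[names(out) == "n"] <- value_name
  out <- out[order(out$patient_id, out$study_day),
             c("patient_id", "study_day", "date", value_name)]
  rownames(out) <- NULL
  out
}

#' Daily medication report counts
#'
#' Counts app-based medication reports per patient-day; a \code{skip}
#' report documents engagement just like a \code{take} and is counted
#' equally. Days without reports yield explicit zeros.
#'
#' @param events Compliance events (filtered internally to medication).
#' @param roster A validated roster.
#' @param config A \code{study_config}.
#' @return Data frame \code{patient_id, study_day, date, medication_reports}.
#' @export
daily_medication_counts <- function(events, roster, config = study_config()) {
  ev <- events[events$event_kind == "medication", , drop = FALSE]
  daily_event_counts(ev, roster, config, "medication_reports")
}

#' Daily symptom-report event counts
#'
#' Each symptom report is a single app interaction and counts exactly once,
#' whether it lists one symptom or eight (or carries a numeric chorea
#' severity).
#'
#' @inheritParams daily_medication_counts
#' @return Data frame \code{patient_id, study_day, date, symptom_events}.
#' @export
daily_symptom_counts <- function(events, roster, config = study_config()) {
  ev <- events[events$event_kind == "symptom", , drop = FALSE]
  daily_event_counts(ev, roster, config, "symptom_events")
}

#' Group assessment task events into performances
#'
#' A structured home assessment comprises two tasks (standing still 30 s,
#' sitting at rest 2 min) performed at one sitting; all assessment events
#' from one patient within \code{assessment_session_minutes} of the
#' session's first event form one performance.
#'
#' @param events Compliance events (filtered internally to assessments).
#' @param config A \code{study_config}.
#' @return Data frame \code{patient_id, session_start, date, n_tasks}, one
#'   row per performance.
#' @export
assessment_sessions <- function(events, config = study_config()) {
  ev <- events[events$event_kind == "assessment", , drop = FALSE]
  if (!nrow(ev))
    return(data.frame(patient_id = character(0),
                      session_start = as.POSIXct(character(0), tz = "UTC"),
                      date = as.Date(character(0)), n_tasks = integer(0)))
  ev <- ev[order(ev$patient_id, ev$timestamp), , drop = FALSE]
  width <- config$assessment_session_minutes * 60
  pieces <- lapply(split(ev, ev$patient_id), function(pe) {
    t <- as.numeric(pe$timestamp)
    session <- integer(length(t))
    sid <- 1L; anchor <- t[1]
    for (i in seq_along(t)) {
      if (t[i] - anchor > width) { sid <- sid + 1L; anchor <- t[i] }
      session[i] <- sid
    }
    starts <- tapply(t, session, min)
    data.frame(patient_id = pe$patient_id[1],
               session_start = as.POSIXct(as.numeric(starts),
                                          origin = "1970-01-01", tz = "UTC"),
               n_tasks = as.integer(tapply(t, session, length)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  out$date <- as.Date(out$session_start, tz = "UTC")
  rownames(out) <- NULL
  out[, c("patient_id", "session_start", "date", "n_tasks")]
}

#' Assessment performances per day, bi-daily block, or trailing window
#'
#' With \code{window_days = 1} this is the per-day performance count used
#' in the daily metrics table. With \code{window_days = 2} performances are
#' tallied in non-overlapping two-day blocks anchored at each patient's
#' enrollment (study days \{1,2\}, \{3,4\}, ...), matching an
#' every-other-day protocol. Larger windows are trailing: the count for a
#' day covers that day and the preceding \code{window_days - 1} days, as
#' used by the 3-assessments-in-8-days monitoring criterion.
#'
#' @param events Compliance events (assessment task events are extracted
#'   and session-grouped internally).
#' @param roster A validated roster.
#' @param window_days Window width in days (1, 2, or a trailing width).
#' @param config A \code{study_config}.
#' @return For \code{window_days <= 2}: data frame with one row per
#'   patient-window and column \code{assessments}; for larger windows one
#'   row per active patient-day with the trailing count.
#' @export
assessment_counts <- function(events, roster, window_days = 1L,
                              config = study_config()) {
  stopifnot(window_days >= 1L)
  sessions <- assessment_sessions(events, config)
  ses_ev <- data.frame(patient_id = sessions$patient_id,
                       timestamp = sessions$session_start,
                       stringsAsFactors = FALSE)
  daily <- daily_event_counts(ses_ev, roster, config, "assessments")
  if (window_days == 1L) return(daily)
  if (window_days == 2L) {
    daily$block <- (daily$study_day - 1L) %/% 2L + 1L
    agg <- stats::aggregate(assessments ~ patient_id + block, daily, sum)
    agg <- agg[order(agg$patient_id, agg$block), , drop = FALSE]
    rownames(agg) <- NULL
    return(agg)
  }
  pieces <- lapply(split(daily, daily$patient_id), function(pd) {
    pd <- pd[order(pd$study_day), , drop = FALSE]
    x <- pd$assessments
    cs <- cumsum(x)
    lag <- pmax(pd$study_day - window_days, 0L)
    pd$assessments <- cs - c(0, cs)[lag + 1L]
    pd
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Assemble the per patient-day compliance metrics table
#'
#' Joins the four compliance metrics on the active patient-day grid:
#' medication reports, symptom events, assessment performances and daily
#' streaming hours (with its waking-window restriction, carried along for
#' the monitoring rule).
#'
#' @param bundle A \code{cohort_bundle}.
#' @param config A \code{study_config}; defaults to the bundle's own.
#' @return Data frame of class \code{daily_metrics} with columns
#'   \code{patient_id, study_day, date, medication_reports, symptom_events,
#'   assessments, streaming_hours, waking_streaming_hours}.
#' @export
daily_metrics <- function(bundle, config = bundle$config) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  med <- daily_medication_counts(bundle$events, bundle$roster, config)
  sym <- daily_symptom_counts(bundle$events, bundle$roster, config)
  ass <- assessment_counts(bundle$events, bundle$roster, 1L, config)
  str <- daily_streaming(bundle$streaming, bundle$charging, bundle$roster,
                         config)
  key <- c("patient_id", "study_day", "date")
  out <- merge(med, sym, by = key)
  out <- merge(out, ass, by = key)
  out <- merge(out, str, by = key)
  out <- out[order(out$patient_id, out$study_day), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- unique(c("daily_metrics", class(out)))
  out
}

#' Names of the per-day metrics in a daily metrics table
#' @param daily A \code{daily_metrics} data frame.
#' @return Character vector of metric column names present with any
#'   non-zero data (assessments are dropped for studies that never
#'   collected them).
#' @export
metric_names <- function(daily) {
  cand <- c("medication_reports", "symptom_events", "assessments",
            "streaming_hours")
  present <- cand[cand %in% names(daily)]
  present[vapply(present, function(m) any(daily[[m]] > 0), TRUE) |
            present %in% c("medication_reports", "symptom_events",
                           "streaming_hours")]
}
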