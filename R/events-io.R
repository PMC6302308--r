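#' @title Event-log and roster input/output
#' @description Readers and writers for the plain-text interchange formats
#'   the pipeline consumes: a patient roster, timestamped app compliance
#'   events, hourly (or raw) accelerometer streaming records, and smartwatch
#'   charging intervals. All timestamps are naive local device time parsed
#'   as ISO-8601; no timezone arithmetic is performed.
#' @name events_io
NULL

EVENT_KINDS <- c("medication", "symptom", "assessment")
MED_ACTIONS <- c("take", "skip")
ASSESSMENT_TASKS <- c("stand_30s", "sit_2min")

# Parse ISO-8601 local timestamps ("2017-06-01T08:30:00" or with a space).
# Device clocks are naive local time; UTC is used purely as a fixed-offset
# container so arithmetic never crosses DST.
parse_timestamp <- function(x) {
  x <- trimws(x)
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01", tz = "UTC")
  ok <- nzchar(x) & !is.na(x)
  if (any(ok)) {
    y <- gsub("T", " ", x[ok], fixed = TRUE)
    parsed <- strptime(y, "%Y-%m-%d %H:%M:%OS", tz = "UTC")
    retry <- is.na(parsed)
    if (any(retry)) parsed[retry] <- strptime(y[retry], "%Y-%m-%d %H:%M",
                                              tz = "UTC")
    out[ok] <- as.POSIXct(parsed)
  }
  out
}

format_timestamp <- function(x) format(x, "%Y-%m-%dT%H:%M:%S", tz = "UTC")

parse_date <- function(x) {
  x <- trimws(x)
  out <- as.Date(rep(NA_integer_, length(x)), origin = "1970-01-01")
  ok <- nzchar(x) & !is.na(x)
  if (any(ok)) out[ok] <- as.Date(x[ok], format = "%Y-%m-%d")
  out
}

check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(what, ": missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  invisible(df)
}

#' Read and validate a patient roster
#'
#' The roster carries one row per enrolled patient: identity, study label,
#' enrollment and (optional) termination dates, and the demographic fields
#' used for covariate correlations. A missing \code{termination_date} means
#' the patient completed the full study.
#'
#' @param path Path to a \code{roster.csv} with columns
#'   \code{patient_id,study,enrollment_date,termination_date,age_years,gender,baseline_severity}.
#' @return A data frame of class \code{patient_roster}.
#' @export
read_roster <- function(path) {
  if (!file.exists(path)) stop("roster file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  check_columns(df, c("patient_id", "study", "enrollment_date",
                      "termination_date"), "roster")
  for (col in c("age_years", "gender", "baseline_severity"))
    if (is.null(df[[col]])) df[[col]] <- NA_character_
  out <- data.frame(
    patient_id = trimws(df$patient_id),
    study = trimws(df$study),
    enrollment_date = parse_date(df$enrollment_date),
    termination_date = parse_date(df$termination_date),
    age_years = suppressWarnings(as.numeric(df$age_years)),
    gender = ifelse(nzchar(trimws(df$gender)), trimws(df$gender), NA_character_),
    baseline_severity = suppressWarnings(as.numeric(df$baseline_severity)),
    stringsAsFactors = FALSE
  )
  validate_roster(out)
}

#' @rdname read_roster
#' @param roster A roster data frame.
#' @return \code{validate_roster} returns the roster invisibly classed as
#'   \code{patient_roster}, or fails listing every offending row.
#' @export
validate_roster <- function(roster) {
  check_columns(roster, c("patient_id", "study", "enrollment_date",
                          "termination_date"), "roster")
  problems <- character(0)
  dup <- unique(roster$patient_id[duplicated(roster$patient_id)])
  if (length(dup))
    problems <- c(problems, paste0("duplicate patient_id: ",
                                   paste(dup, collapse = ", ")))
  bad_enr <- which(is.na(roster$enrollment_date))
  if (length(bad_enr))
    problems <- c(problems, paste0("missing/unparsable enrollment_date at row(s) ",
                                   paste(bad_enr, collapse = ", ")))
  bad_term <- which(!is.na(roster$termination_date) &
                    roster$termination_date < roster$enrollment_date)
  if (length(bad_term))
    problems <- c(problems,
                  paste0("termination_date before enrollment_date at row(s) ",
                         paste(bad_term, collapse = ", ")))
  if (!is.null(roster$age_years)) {
    bad_age <- which(!is.na(roster$age_years) & roster$age_years < 0)
    if (length(bad_age))
      problems <- c(problems, paste0("negative age_years at row(s) ",
                                     paste(bad_age, collapse = ", ")))
  }
  if (length(problems))
    stop("invalid roster:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  class(roster) <- unique(c("patient_roster", class(roster)))
  invisible(roster)
}

#' @rdname read_roster
#' @export
write_roster <- function(roster, path) {
  validate_roster(roster)
  out <- data.frame(
    patient_id = roster$patient_id,
    study = roster$study,
    enrollment_date = format(roster$enrollment_date, "%Y-%m-%d"),
    termination_date = ifelse(is.na(roster$termination_date), "",
                              format(roster$termination_date, "%Y-%m-%d")),
    age_years = roster$age_years,
    gender = ifelse(is.na(roster$gender), "", roster$gender),
    baseline_severity = roster$baseline_severity,
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read and validate app compliance events
#'
#' Events are timestamped smartphone-app interactions of three kinds:
#' medication reports (action \code{take} or \code{skip} -- both count as a
#' report), symptom reports (payload: semicolon-joined symptom labels, at
#' most eight, or a numeric chorea-severity value), and structured
#' home-assessment task events (payload: \code{stand_30s} or
#' \code{sit_2min}).
#'
#' @param path Path to an \code{events.csv} with columns
#'   \code{patient_id,timestamp,event_kind,action,payload}.
#' @param kind_filter Optional single event kind to keep.
#' @return A data frame of class \code{compliance_events}, sorted by
#'   \code{(patient_id, timestamp)}.
#' @export
read_events <- function(path, kind_filter = NULL) {
  if (!file.exists(path)) stop("events file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  check_columns(df, c("patient_id", "timestamp", "event_kind"), "events")
  if (is.null(df$action)) df$action <- ""
  if (is.null(df$payload)) df$payload <- ""
  ts <- parse_timestamp(df$timestamp)
  bad_ts <- which(is.na(ts) & nrow(df) > 0)
  if (length(bad_ts))
    stop("events: unparsable timestamp at line(s) ",
         paste(bad_ts + 1L, collapse = ", "), " (header = line 1)",
         call. = FALSE)
  out <- data.frame(
    patient_id = trimws(df$patient_id),
    timestamp = ts,
    event_kind = trimws(df$event_kind),
    action = trimws(df$action),
    payload = trimws(df$payload),
    stringsAsFactors = FALSE
  )
  out$action[!nzchar(out$action)] <- NA_character_
  out <- validate_events(out)
  if (!is.null(kind_filter)) {
    kind_filter <- match.arg(kind_filter, EVENT_KINDS)
    out <- out[out$event_kind == kind_filter, , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' @rdname read_events
#' @param events An events data frame.
#' @export
validate_events <- function(events) {
  check_columns(events, c("patient_id", "timestamp", "event_kind"), "events")
  problems <- character(0)
  unknown <- setdiff(unique(events$event_kind), EVENT_KINDS)
  if (length(unknown))
    problems <- c(problems, paste0("unknown event_kind: ",
                                   paste(unknown, collapse = ", ")))
  is_med <- events$event_kind == "medication"
  bad_action <- which(is_med & !(events$action %in% MED_ACTIONS))
  if (length(bad_action))
    problems <- c(problems,
                  paste0("medication rows need action take|skip at row(s) ",
                         paste(bad_action, collapse = ", ")))
  stray_action <- which(!is_med & !is.na(events$action))
  if (length(stray_action))
    problems <- c(problems, paste0("action present on non-medication row(s) ",
                                   paste(stray_action, collapse = ", ")))
  is_sym <- events$event_kind == "symptom"
  if (any(is_sym)) {
    payload <- events$payload[is_sym]
    n_labels <- vapply(strsplit(payload, ";", fixed = TRUE), function(p) {
      length(p[nzchar(trimws(p))])
    }, 1L)
    # a single numeric severity payload is one "label"
    bad_sym <- which(is_sym)[n_labels < 1L | n_labels > 8L]
    if (length(bad_sym))
      problems <- c(problems,
                    paste0("symptom payload must carry 1-8 entries at row(s) ",
                           paste(bad_sym, collapse = ", ")))
  }
  is_ass <- events$event_kind == "assessment"
  bad_task <- which(is_ass & !(events$payload %in% ASSESSMENT_TASKS))
  if (length(bad_task))
    problems <- c(problems,
                  paste0("assessment payload must be one of ",
                         paste(ASSESSMENT_TASKS, collapse = "|"),
                         " at row(s) ", paste(bad_task, collapse = ", ")))
  if (length(problems))
    stop("invalid events:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  o <- order(events$patient_id, events$timestamp)
  events <- events[o, , drop = FALSE]
  rownames(events) <- NULL
  class(events) <- unique(c("compliance_events", class(events)))
  events
}

#' @rdname read_events
#' @export
write_events <- function(events, path) {
  events <- validate_events(events)
  out <- data.frame(
    patient_id = events$patient_id,
    timestamp = format_timestamp(events$timestamp),
    event_kind = events$event_kind,
    action = ifelse(is.na(events$action), "", events$action),
    payload = events$payload,
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read accelerometer streaming records
#'
#' Accepts either of two dialects, inferred from the header: pre-binned
#' hourly counts (\code{patient_id,hour_start,record_count}) or raw sample
#' timestamps (\code{patient_id,timestamp}), which are binned to half-open
#' clock-hour bins \code{[h:00, h+1:00)}.
#'
#' @param path Path to \code{streaming_hours.csv} or \code{streaming_raw.csv}.
#' @param config A \code{study_config}; the sampling rate bounds admissible
#'   counts (an hour cannot hold more than \code{rate * 3600} records).
#' @return A data frame \code{patient_id, hour_start, record_count} with at
#'   most one row per patient-hour.
#' @export
read_streaming <- function(path, config = study_config()) {
  if (!file.exists(path)) stop("streaming file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  if ("record_count" %in% names(df)) {
    check_columns(df, c("patient_id", "hour_start", "record_count"), "streaming")
    out <- data.frame(
      patient_id = trimws(df$patient_id),
      hour_start = parse_timestamp(df$hour_start),
      record_count = suppressWarnings(as.numeric(df$record_count)),
      stringsAsFactors = FALSE
    )
    if (anyNA(out$hour_start))
      stop("streaming: unparsable hour_start at line(s) ",
           paste(which(is.na(out$hour_start)) + 1L, collapse = ", "),
           call. = FALSE)
  } else {
    check_columns(df, c("patient_id", "timestamp"), "streaming")
    ts <- parse_timestamp(df$timestamp)
    if (anyNA(ts))
      stop("streaming: unparsable timestamp at line(s) ",
           paste(which(is.na(ts)) + 1L, collapse = ", "), call. = FALSE)
    out <- bin_streaming_raw(data.frame(patient_id = trimws(df$patient_id),
                                        timestamp = ts,
                                        stringsAsFactors = FALSE))
  }
  validate_streaming(out, config)
}

#' @rdname read_streaming
#' @param raw Data frame \code{patient_id, timestamp} of raw sample times.
#' @return \code{bin_streaming_raw} returns hourly counts; summing them
#'   reproduces the raw sample count exactly.
#' @export
bin_streaming_raw <- function(raw) {
  hour_start <- as.POSIXct(trunc(raw$timestamp, units = "hours"))
  agg <- stats::aggregate(list(record_count = rep(1L, nrow(raw))),
                          by = list(patient_id = raw$patient_id,
                                    hour_start = hour_start),
                          FUN = sum)
  agg <- agg[order(agg$patient_id, agg$hour_start), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' @rdname read_streaming
#' @param streaming Pre-binned streaming data frame.
#' @export
validate_streaming <- function(streaming, config = study_config()) {
  check_columns(streaming, c("patient_id", "hour_start", "record_count"),
                "streaming")
  max_records <- config$sampling_rate_hz * 3600
  problems <- character(0)
  bad_n <- which(is.na(streaming$record_count) | streaming$record_count < 0 |
                 streaming$record_count > max_records)
  if (length(bad_n))
    problems <- c(problems,
                  paste0("record_count outside [0, ", max_records,
                         "] at row(s) ", paste(bad_n, collapse = ", ")))
  key <- paste(streaming$patient_id, format_timestamp(streaming$hour_start))
  dup <- which(duplicated(key))
  if (length(dup))
    problems <- c(problems, paste0("duplicate (patient_id, hour_start) at row(s) ",
                                   paste(dup, collapse = ", ")))
  if (length(problems))
    stop("invalid streaming records:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  streaming <- streaming[order(streaming$patient_id, streaming$hour_start), ,
                         drop = FALSE]
  rownames(streaming) <- NULL
  streaming
}

#' @rdname read_streaming
#' @export
write_streaming <- function(streaming, path) {
  out <- data.frame(
    patient_id = streaming$patient_id,
    hour_start = format_timestamp(streaming$hour_start),
    record_count = streaming$record_count,
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read smartwatch charging intervals
#'
#' @param path Path to a \code{charging.csv} with columns
#'   \code{patient_id,start,end}.
#' @return A data frame \code{patient_id, start, end} with \code{end > start}.
#' @export
read_charging <- function(path) {
  if (!file.exists(path)) stop("charging file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  check_columns(df, c("patient_id", "start", "end"), "charging")
  out <- data.frame(
    patient_id = trimws(df$patient_id),
    start = parse_timestamp(df$start),
    end = parse_timestamp(df$end),
    stringsAsFactors = FALSE
  )
  bad <- which(is.na(out$start) | is.na(out$end) | out$end <= out$start)
  if (length(bad))
    stop("charging: invalid interval at line(s) ",
         paste(bad + 1L, collapse = ", "), call. = FALSE)
  out[order(out$patient_id, out$start), , drop = FALSE]
}

#' @rdname read_charging
#' @param charging A charging-interval data frame.
#' @export
write_charging <- function(charging, path) {
  out <- data.frame(
    patient_id = charging$patient_id,
    start = format_timestamp(charging$start),
    end = format_timestamp(charging$end),
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Merge a patient's charging intervals to non-overlapping form
#' @param charging Charging intervals for any number of patients.
#' @return The same frame with per-patient overlapping intervals coalesced.
#' @export
merge_charging <- function(charging) {
  if (nrow(charging) == 0L) return(charging)
  pieces <- lapply(split(charging, charging$patient_id), function(ci) {
    ci <- ci[order(ci$start), , drop = FALSE]
    start <- ci$start[1]; end <- ci$end[1]
    keep <- list()
    for (i in seq_len(nrow(ci))[-1]) {
      if (ci$start[i] <= end) {
        end <- max(end, ci$end[i])
      } else {
        keep[[length(keep) + 1L]] <- c(start, end)
        start <- ci$start[i]; end <- ci$end[i]
      }
    }
    keep[[length(keep) + 1L]] <- c(start, end)
    data.frame(patient_id = ci$patient_id[1],
               start = as.POSIXct(vapply(keep, `[`, numeric(1), 1L),
                                  origin = "1970-01-01", tz = "UTC"),
               end = as.POSIXct(vapply(keep, `[`, numeric(1), 2L),
                                origin = "1970-01-01", tz = "UTC"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Enrolled, uncensored patient-days
#'
#' A patient is active on a calendar date from their enrollment date up to,
#' but not including, their termination date (dropouts are censored from
#' the dropout date onward); completers are active for the full protocol
#' length.
#'
#' @param roster A validated roster.
#' @param config A \code{study_config}.
#' @return Data frame \code{patient_id, date, study_day} with one row per
#'   active patient-day (study day 1 is the enrollment date).
#' @export
patient_days <- function(roster, config = study_config()) {
  pieces <- lapply(seq_len(nrow(roster)), function(i) {
    enr <- roster$enrollment_date[i]
    term <- roster$termination_date[i]
    last <- enr + config$study_length_days - 1L
    if (!is.na(term)) last <- min(last, term - 1L)
    if (last < enr) return(NULL)
    dates <- seq(enr, last, by = "day")
    data.frame(patient_id = roster$patient_id[i],
               date = dates,
               study_day = as.integer(dates - enr) + 1L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Bundle the four input tables of one study
#'
#' @param roster,events,streaming,charging The four component tables; any of
#'   the latter three may be empty data frames.
#' @param config Optional \code{study_config} carried with the bundle.
#' @return An object of class \code{cohort_bundle}.
#' @export
cohort_bundle <- function(roster, events, streaming, charging,
                          config = study_config()) {
  roster <- validate_roster(roster)
  events <- validate_events(events)
  streaming <- validate_streaming(streaming, config)
  unknown <- setdiff(unique(c(events$patient_id, streaming$patient_id,
                              charging$patient_id)),
                     roster$patient_id)
  if (length(unknown))
    stop("records for patients absent from roster: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  structure(list(roster = roster, events = events, streaming = streaming,
                 charging = charging, config = config),
            class = "cohort_bundle")
}

#' @export
print.cohort_bundle <- function(x, ...) {
  n_done <- sum(is.na(x$roster$termination_date))
  cat(sprintf("Cohort bundle: %d patients (%s), %d completed\n",
              nrow(x$roster), paste(unique(x$roster$study), collapse = ", "),
              n_done))
  cat(sprintf("  events:    %d (%s)\n", nrow(x$events),
              paste(sprintf("%s %d", names(table(x$events$event_kind)),
                            table(x$events$event_kind)), collapse = ", ")))
  cat(sprintf("  streaming: %d patient-hours\n", nrow(x$streaming)))
  cat(sprintf("  charging:  %d intervals\n", nrow(x$charging)))
  invisible(x)
}

#' Read or write a full input bundle from a directory
#'
#' Uses the canonical file names \code{roster.csv}, \code{events.csv},
#' \code{streaming_hours.csv} (or \code{streaming_raw.csv}) and
#' \code{charging.csv}.
#'
#' @param dir Directory holding the bundle.
#' @param config A \code{study_config}.
#' @return \code{read_bundle} returns a \code{cohort_bundle}.
#' @export
read_bundle <- function(dir, config = study_config()) {
  roster <- read_roster(file.path(dir, "roster.csv"))
  events <- read_events(file.path(dir, "events.csv"))
  sh <- file.path(dir, "streaming_hours.csv")
  sr <- file.path(dir, "streaming_raw.csv")
  streaming <- read_streaming(if (file.exists(sh)) sh else sr, config)
  charging <- read_charging(file.path(dir, "charging.csv"))
  cohort_bundle(roster, events, streaming, charging, config)
}

#' @rdname read_bundle
#' @param bundle A \code{cohort_bundle}.
#' @export
write_bundle <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_roster(bundle$roster, file.path(dir, "roster.csv"))
  write_events(bundle$events, file.path(dir, "events.csv"))
  write_streaming(bundle$streaming, file.path(dir, "streaming_hours.csv"))
  write_charging(bundle$charging, file.path(dir, "charging.csv"))
  write_study_config(bundle$config, file.path(dir, "study_config.txt"))
  invisible(dir)
}
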