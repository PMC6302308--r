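#' @title Daily smartwatch streaming hours
#' @description The streaming metric counts, per patient-day, the clock
#'   hours in which the smartwatch streamed accelerometer data, excluding
#'   charging time. An hour counts only if it carries at least
#'   \code{valid_hour_fraction} (default 90\%) of the records expected at
#'   the device sampling rate; charging time prorates both the expectation
#'   and the hour's maximum contribution.
#' @name streaming_metrics
NULL

#' Validity contribution of one streaming hour
#'
#' An hour with charging fraction \eqn{c} can contribute at most
#' \eqn{1 - c} hours of streaming. It contributes that amount when the
#' observed record count reaches \code{valid_hour_fraction} of the prorated
#' expectation \eqn{rate \times 3600 \times (1 - c)}, and 0 otherwise. At
#' 50 Hz with no charging the threshold is 162,000 records.
#'
#' @param record_count Records observed in the hour (vectorized).
#' @param charging_fraction Fraction of the hour covered by (merged)
#'   charging intervals, in [0, 1].
#' @param config A \code{study_config}.
#' @return Contribution in [0, 1] hours, same length as the inputs.
#' @examples
#' hour_validity(162000, 0)  # exactly the 90% threshold -> 1
#' hour_validity(161999, 0)  # one record short -> 0
#' hour_validity(81000, 0.5) # half the hour charging -> 0.5
#' @export
hour_validity <- function(record_count, charging_fraction,
                          config = study_config()) {
  stopifnot(all(charging_fraction >= 0 & charging_fraction <= 1))
  effective <- 1 - charging_fraction
  expected <- config$sampling_rate_hz * 3600 * effective
  ok <- effective > 0 & record_count >= config$valid_hour_fraction * expected
  ifelse(ok, effective, 0)
}

# Fraction of each clock hour covered by charging, per patient.
# Intervals are merged first so overlaps never double-count.
charging_hour_fractions <- function(charging) {
  if (is.null(charging) || nrow(charging) == 0L)
    return(data.frame(patient_id = character(0),
                      hour_start = as.POSIXct(character(0), tz = "UTC"),
                      charging_fraction = numeric(0),
                      stringsAsFactors = FALSE))
  charging <- merge_charging(charging)
  pieces <- lapply(seq_len(nrow(charging)), function(i) {
    s <- charging$start[i]; e <- charging$end[i]
    first <- as.POSIXct(trunc(s, units = "hours"))
    hours <- seq(first, as.POSIXct(trunc(e - 1e-6, units = "hours")),
                 by = 3600)
    overlap <- pmin(as.numeric(e), as.numeric(hours) + 3600) -
      pmax(as.numeric(s), as.numeric(hours))
    data.frame(patient_id = charging$patient_id[i], hour_start = hours,
               charging_fraction = overlap / 3600, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  agg <- stats::aggregate(charging_fraction ~ patient_id + hour_start, out, sum)
  agg$charging_fraction <- pmin(agg$charging_fraction, 1)
  agg
}

#' Daily streaming hours per patient
#'
#' Sums hour-validity contributions over each active patient-day, both in
#' total and restricted to the waking window. Every enrolled, uncensored
#' day appears in the output, with explicit zeros on days without any valid
#' streaming hour; hours recorded outside a patient's active period are
#' dropped.
#'
#' @param streaming Hourly record counts (see \code{\link{read_streaming}}).
#' @param charging Charging intervals, possibly empty.
#' @param roster A validated patient roster.
#' @param config A \code{study_config}.
#' @return Data frame \code{patient_id, study_day, date, streaming_hours,
#'   waking_streaming_hours} with one row per active patient-day.
#' @export
daily_streaming <- function(streaming, charging, roster,
                            config = study_config()) {
  roster <- validate_roster(roster)
  unknown <- setdiff(unique(streaming$patient_id), roster$patient_id)
  if (length(unknown))
    stop("streaming records for patients absent from roster: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  grid <- patient_days(roster, config)
  if (nrow(streaming)) {
    cf <- charging_hour_fractions(charging)
    m <- merge(streaming, cf, by = c("patient_id", "hour_start"), all.x = TRUE)
    m$charging_fraction[is.na(m$charging_fraction)] <- 0
    m$contribution <- hour_validity(m$record_count, m$charging_fraction, config)
    m$date <- as.Date(m$hour_start, tz = "UTC")
    hr <- as.integer(format(m$hour_start, "%H", tz = "UTC"))
    m$waking <- m$contribution *
      (hr >= config$waking_window[1] & hr < config$waking_window[2])
    agg <- stats::aggregate(cbind(streaming_hours = contribution,
                                  waking_streaming_hours = waking) ~
                              patient_id + date, data = m, FUN = sum)
  } else {
    agg <- data.frame(patient_id = character(0),
                      date = as.Date(character(0)),
                      streaming_hours = numeric(0),
                      waking_streaming_hours = numeric(0))
  }
  out <- merge(grid, agg, by = c("patient_id", "date"), all.x = TRUE)
  out$streaming_hours[is.na(out$streaming_hours)] <- 0
  out$waking_streaming_hours[is.na(out$waking_streaming_hours)] <- 0
  out <- out[order(out$patient_id, out$study_day),
             c("patient_id", "study_day", "date",
               "streaming_hours", "waking_streaming_hours")]
  rownames(out) <- NULL
  out
}
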