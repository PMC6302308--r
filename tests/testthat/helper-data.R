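# Small in-code fixtures shared across test files.

ts_utc <- function(x) as.POSIXct(x, tz = "UTC")

make_roster <- function(n = 2, enroll = as.Date("2017-06-05"),
                        term = rep(NA, n), study = "PD-study") {
  validate_roster(data.frame(
    patient_id = sprintf("P%02d", seq_len(n)),
    study = study,
    enrollment_date = rep(enroll, length.out = n),
    termination_date = as.Date(term),
    age_years = 60 + seq_len(n),
    gender = rep(c("female", "male"), length.out = n),
    baseline_severity = 20 + seq_len(n),
    stringsAsFactors = FALSE))
}

make_events <- function(patient_id, times, kind, action = NA_character_,
                        payload = "") {
  df <- data.frame(patient_id = patient_id, timestamp = ts_utc(times),
                   event_kind = kind, action = action, payload = payload,
                   stringsAsFactors = FALSE)
  df$payload[df$event_kind == "symptom" & !nzchar(df$payload)] <- "tremor"
  df$payload[df$event_kind == "assessment" & !nzchar(df$payload)] <- "stand_30s"
  validate_events(df)
}

empty_events <- function() {
  data.frame(patient_id = character(0),
             timestamp = ts_utc(character(0)),
             event_kind = character(0), action = character(0),
             payload = character(0), stringsAsFactors = FALSE)
}

empty_charging <- function() {
  data.frame(patient_id = character(0), start = ts_utc(character(0)),
             end = ts_utc(character(0)), stringsAsFactors = FALSE)
}

# n_hours fully valid streaming hours for one patient-date, starting at
# clock hour `from`
valid_hours <- function(patient_id, date, from = 0L, n_hours = 24L,
                        count = 180000) {
  data.frame(patient_id = patient_id,
             hour_start = ts_utc(paste(date, "00:00:00")) +
               (from + seq_len(n_hours) - 1L) * 3600,
             record_count = count, stringsAsFactors = FALSE)
}
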