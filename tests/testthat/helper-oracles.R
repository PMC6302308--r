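# Independent brute-force oracles, kept deliberately naive: they enumerate
# what the implementation computes with interval arithmetic or library calls.

# Per-second enumeration of streaming/charging state: for every clock hour
# of every active patient-day, charging coverage is measured by walking the
# 3600 seconds of the hour, then the completeness rule is applied and
# summed per day.
oracle_daily_streaming <- function(streaming, charging, roster, config) {
  grid <- patient_days(roster, config)
  key <- paste(streaming$patient_id, as.numeric(streaming$hour_start))
  out <- grid
  out$streaming_hours <- 0
  out$waking_streaming_hours <- 0
  for (r in seq_len(nrow(grid))) {
    pid <- grid$patient_id[r]
    day0 <- as.numeric(ts_utc(paste(grid$date[r], "00:00:00")))
    ch <- charging[charging$patient_id == pid, , drop = FALSE]
    total <- 0
    waking <- 0
    for (h in 0:23) {
      hs <- day0 + h * 3600
      idx <- match(paste(pid, hs), key)
      count <- if (is.na(idx)) 0 else streaming$record_count[idx]
      secs <- hs + 0:3599
      charged <- rep(FALSE, 3600)
      for (k in seq_len(nrow(ch)))
        charged <- charged | (secs >= as.numeric(ch$start[k]) &
                                secs < as.numeric(ch$end[k]))
      eff <- 1 - mean(charged)
      expected <- config$sampling_rate_hz * 3600 * eff
      contrib <- if (eff > 0 && count >= config$valid_hour_fraction * expected)
        eff else 0
      total <- total + contrib
      if (h >= config$waking_window[1] && h < config$waking_window[2])
        waking <- waking + contrib
    }
    out$streaming_hours[r] <- total
    out$waking_streaming_hours[r] <- waking
  }
  out[order(out$patient_id, out$study_day),
      c("patient_id", "study_day", "date", "streaming_hours",
        "waking_streaming_hours")]
}

# Random 1-3 day single-patient instance with record counts concentrated
# near the validity threshold and 0-3 charging intervals per day.
random_streaming_instance <- function() {
  n_days <- sample(1:3, 1)
  enroll <- as.Date("2017-06-05")
  roster <- make_roster(1, enroll = enroll)
  cfg <- study_config(study_length_days = n_days)
  rows <- list()
  ch <- list()
  for (d in seq_len(n_days)) {
    date <- enroll + d - 1
    hours <- sort(sample(0:23, sample(4:20, 1)))
    counts <- sample(c(
      sample(0:180000, length(hours), replace = TRUE),
      round(162000 * stats::runif(length(hours), 0.9, 1.1))),
      length(hours))
    counts <- pmin(counts, 180000)
    rows[[d]] <- data.frame(patient_id = "P01",
                            hour_start = ts_utc(paste(date, "00:00:00")) +
                              hours * 3600,
                            record_count = counts, stringsAsFactors = FALSE)
    for (k in seq_len(sample(0:3, 1))) {
      # whole-second endpoints so per-second enumeration is exact
      s <- ts_utc(paste(date, "00:00:00")) + sample(0:82800, 1)
      ch[[length(ch) + 1L]] <- data.frame(
        patient_id = "P01", start = s,
        end = s + sample(60:14400, 1), stringsAsFactors = FALSE)
    }
  }
  list(streaming = do.call(rbind, rows),
       charging = if (length(ch)) do.call(rbind, ch) else empty_charging(),
       roster = roster, config = cfg)
}

# rank-then-Pearson Spearman with average ranks on ties
oracle_spearman <- function(x, y) {
  stats::cor(rank(x), rank(y), method = "pearson")
}

# direct arithmetic-mean trailing window
oracle_moving_avg <- function(x, w) {
  vapply(seq_along(x), function(i) mean(x[max(1, i - w + 1):i]), numeric(1))
}

# enumeration of the weighted day-flag score
oracle_score <- function(flags, weights = c(4, 2, 1)) {
  sum(weights * as.integer(flags))
}
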