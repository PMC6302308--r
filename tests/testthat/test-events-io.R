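test_that("roster reading parses completed and terminated patients", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "patient_id,study,enrollment_date,termination_date,age_years,gender,baseline_severity",
    "P01,PD-study,2017-06-05,,62,female,24",
    "P02,PD-study,2017-06-08,2017-07-01,70,male,31"), path)
  roster <- read_roster(path)
  expect_s3_class(roster, "patient_roster")
  expect_equal(nrow(roster), 2)
  expect_true(is.na(roster$termination_date[1]))
  expect_equal(roster$termination_date[2], as.Date("2017-07-01"))
  expect_equal(roster$age_years, c(62, 70))
})

test_that("roster validation rejects bad rows, listing all offenders", {
  roster <- make_roster(3)
  roster$termination_date[c(1, 3)] <- roster$enrollment_date[c(1, 3)] - 1
  err <- tryCatch(validate_roster(roster), error = identity)
  expect_match(conditionMessage(err), "termination_date before enrollment")
  expect_match(conditionMessage(err), "1, 3")

  dup <- make_roster(2)
  dup$patient_id <- c("P01", "P01")
  expect_error(validate_roster(dup), "duplicate patient_id")

  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("patient_id,study", "P01,PD-study"), path)
  expect_error(read_roster(path), "enrollment_date")
})

test_that("a 51-row roster yields 51 records and round-trips", {
  roster <- make_roster(51)
  path <- withr::local_tempfile(fileext = ".csv")
  write_roster(roster, path)
  back <- read_roster(path)
  expect_equal(nrow(back), 51)
  expect_equal(back$patient_id, roster$patient_id)
  expect_equal(back$enrollment_date, roster$enrollment_date)
  expect_equal(back$termination_date, roster$termination_date)
})

test_that("event reading handles empty files, skip reports, and filters", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("patient_id,timestamp,event_kind,action,payload", path)
  expect_equal(nrow(read_events(path)), 0)

  writeLines(c("patient_id,timestamp,event_kind,action,payload",
               "P01,2017-06-05T08:30:00,medication,skip,",
               "P01,2017-06-05T07:30:00,symptom,,tremor;rigidity"), path)
  ev <- read_events(path)
  # sorted by (patient, time): symptom first
  expect_equal(ev$event_kind, c("symptom", "medication"))
  expect_equal(ev$action, c(NA, "skip"))
  med <- read_events(path, kind_filter = "medication")
  expect_equal(nrow(med), 1)
  expect_equal(med$action, "skip")
})

test_that("event validation enforces kind, action and payload invariants", {
  nine <- paste(sprintf("s%d", 1:9), collapse = ";")
  expect_error(make_events("P01", "2017-06-05 09:00:00", "symptom",
                           payload = nine), "1-8")
  expect_error(validate_events(data.frame(
    patient_id = "P01", timestamp = ts_utc("2017-06-05 09:00:00"),
    event_kind = "sleep", action = NA_character_, payload = "",
    stringsAsFactors = FALSE)), "unknown event_kind")
  expect_error(make_events("P01", "2017-06-05 09:00:00", "medication",
                           action = "taken"), "take\\|skip")
  expect_error(make_events("P01", "2017-06-05 09:00:00", "symptom",
                           action = "take"), "non-medication")

  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("patient_id,timestamp,event_kind,action,payload",
               "P01,yesterday,medication,take,"), path)
  expect_error(read_events(path), "line.*2")
})

test_that("raw streaming timestamps bin to clock hours conservatively", {
  base <- ts_utc("2017-06-05 14:00:00")
  # 162000 samples in hour 14, 90000 in hour 15
  raw <- data.frame(
    patient_id = "P01",
    timestamp = c(base + seq(0, 3599.98, length.out = 162000),
                  base + 3600 + seq(0, 3599.98, length.out = 90000)))
  binned <- bin_streaming_raw(raw)
  expect_equal(binned$record_count, c(162000, 90000))
  expect_equal(binned$hour_start, c(base, base + 3600))
  # conservation under arbitrary random times
  set.seed(1)
  raw2 <- data.frame(patient_id = sample(c("A", "B"), 500, TRUE),
                     timestamp = base + stats::runif(500, 0, 86400 * 2))
  expect_equal(sum(bin_streaming_raw(raw2)$record_count), 500)
})

test_that("streaming validation enforces the physical maximum and uniqueness", {
  s <- valid_hours("P01", as.Date("2017-06-05"), n_hours = 2)
  expect_silent(validate_streaming(s))
  s2 <- s; s2$record_count[1] <- 180001
  expect_error(validate_streaming(s2), "record_count")
  s3 <- rbind(s, s[1, ])
  expect_error(validate_streaming(s3), "duplicate")
})

test_that("charging intervals validate and merge to non-overlapping form", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("patient_id,start,end",
               "P01,2017-06-05T22:00:00,2017-06-05T23:30:00",
               "P01,2017-06-05T23:00:00,2017-06-06T00:15:00",
               "P01,2017-06-06T10:00:00,2017-06-06T10:30:00"), path)
  ch <- read_charging(path)
  merged <- merge_charging(ch)
  expect_equal(nrow(merged), 2)
  expect_equal(merged$end[1], ts_utc("2017-06-06 00:15:00"))
  writeLines(c("patient_id,start,end",
               "P01,2017-06-05T22:00:00,2017-06-05T22:00:00"), path)
  expect_error(read_charging(path), "invalid interval")
})

test_that("a full bundle round-trips through a directory byte-faithfully", {
  bundle <- simulate_hd_profile(seed = 9, n_patients = 3,
                                study_length_days = 30)
  dir <- withr::local_tempdir()
  write_bundle(bundle, dir)
  back <- read_bundle(dir, bundle$config)
  expect_equal(back$roster$patient_id, bundle$roster$patient_id)
  expect_equal(back$roster$termination_date, bundle$roster$termination_date)
  expect_equal(back$events$timestamp, bundle$events$timestamp)
  expect_equal(back$events$payload, bundle$events$payload)
  expect_equal(back$streaming$record_count, bundle$streaming$record_count)
  expect_equal(back$charging$start, bundle$charging$start)
})

test_that("patient-day grids censor from the termination date onward", {
  roster <- make_roster(2, enroll = as.Date("2017-06-05"),
                        term = c(NA, "2017-06-10"))
  cfg <- study_config(study_length_days = 20)
  grid <- patient_days(roster, cfg)
  expect_equal(sum(grid$patient_id == "P01"), 20)
  # terminated on day 6: active days 1..5
  expect_equal(sum(grid$patient_id == "P02"), 5)
  expect_equal(max(grid$date[grid$patient_id == "P02"]),
               as.Date("2017-06-09"))
  expect_equal(grid$study_day[grid$date == as.Date("2017-06-05") &
                                grid$patient_id == "P01"], 1L)
})
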