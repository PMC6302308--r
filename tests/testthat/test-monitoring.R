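test_that("compliant-day boundary sits at 90% of the waking window, inclusive", {
  expect_true(is_compliant_day(10.8))
  expect_false(is_compliant_day(10.79))
  expect_true(is_compliant_day(12))
  expect_false(is_compliant_day(0))
  # the boundary follows the configured window and fraction
  cfg <- study_config(waking_window = c(8, 22), valid_hour_fraction = 0.5)
  expect_true(is_compliant_day(7, cfg))
  expect_false(is_compliant_day(6.99, cfg))
})

test_that("all eight day-flag patterns score per the 4/2/1 weighting", {
  cfg <- study_config()
  patterns <- expand.grid(d1 = c(FALSE, TRUE), d2 = c(FALSE, TRUE),
                          d3 = c(FALSE, TRUE))
  scores <- apply(patterns, 1, function(p) streaming_score(as.logical(p), cfg))
  wanted <- apply(patterns, 1, function(p) oracle_score(as.logical(p)))
  expect_equal(scores, wanted)
  expect_setequal(scores, 0:7)
  expect_equal(streaming_score(c(FALSE, FALSE, FALSE), cfg), 0)
  expect_equal(streaming_score(c(TRUE, FALSE, FALSE), cfg), 4)
  expect_equal(streaming_score(c(TRUE, TRUE, TRUE), cfg), 7)
})

test_that("scores are monotone in day compliance", {
  cfg <- study_config()
  for (i in 1:8) {
    flags <- as.logical(intToBits(i - 1)[1:3])
    base <- streaming_score(flags, cfg)
    for (j in which(!flags)) {
      up <- flags; up[j] <- TRUE
      expect_gt(streaming_score(up, cfg), base)
    }
  }
})

# build a one-patient scenario with chosen compliant dates and assessment
# performance dates, query on a fixed Monday
monitor_case <- function(ok_days, assess_days, enroll = as.Date("2017-06-05")) {
  roster <- make_roster(1, enroll = enroll, study = "HD-study")
  cfg <- study_config(study_length_days = 30)
  streaming <- do.call(rbind, lapply(ok_days, function(d)
    valid_hours("P01", enroll + d - 1, from = 9L, n_hours = 12L)))
  if (is.null(streaming))
    streaming <- valid_hours("P01", enroll, from = 9L, n_hours = 0L)[0, ]
  ds <- daily_streaming(streaming, empty_charging(), roster, cfg)
  ev <- if (length(assess_days))
    make_events("P01", paste(enroll + assess_days - 1, "09:00:00"),
                "assessment", payload = "stand_30s") else empty_events()
  query <- enroll + 14  # 2017-06-19, a Monday
  run_monitoring(ds, ev, roster, cfg, schedule = query,
                 include_assessments = TRUE)
}

test_that("monitoring flags follow the two protocol criteria", {
  # compliant yesterday and 3 days ago: 4 + 1 = 5, three recent assessments
  r <- monitor_case(ok_days = c(12, 14), assess_days = c(9, 11, 13))
  expect_equal(r$score, 5)
  expect_false(r$streaming_flag)
  expect_equal(r$assessment_count_8d, 3L)
  expect_false(r$assessment_flag)
  expect_false(r$contact_recommended)

  # score 2 (two days ago only) with enough assessments: streaming flag only
  r2 <- monitor_case(ok_days = 13, assess_days = c(9, 11, 13, 15))
  expect_equal(r2$score, 2)
  expect_true(r2$streaming_flag)
  expect_false(r2$assessment_flag)
  expect_true(r2$contact_recommended)

  # score 7 but two assessments: assessment flag only
  r3 <- monitor_case(ok_days = 12:14, assess_days = c(9, 13))
  expect_equal(r3$score, 7)
  expect_false(r3$streaming_flag)
  expect_true(r3$assessment_flag)
  expect_true(r3$contact_recommended)

  # exactly at both thresholds: score 3 (d2 + d3), 3 assessments: no flags
  r4 <- monitor_case(ok_days = c(12, 13), assess_days = c(10, 12, 14))
  expect_equal(r4$score, 3)
  expect_false(r4$contact_recommended)
})

test_that("the assessment lookback spans exactly eight trailing days", {
  # query day 15: window covers days 8..15; a performance on day 7 is out
  r <- monitor_case(ok_days = 12:14, assess_days = c(7, 8, 15))
  expect_equal(r$assessment_count_8d, 2L)
  expect_true(r$assessment_flag)
})

test_that("days before enrollment count as non-compliant in early queries", {
  enroll <- as.Date("2017-06-16")  # Friday; first Monday is study day 4
  roster <- make_roster(1, enroll = enroll)
  cfg <- study_config(study_length_days = 30)
  streaming <- valid_hours("P01", enroll + 2, from = 9L, n_hours = 12L)
  ds <- daily_streaming(streaming, empty_charging(), roster, cfg)
  r <- run_monitoring(ds, empty_events(), roster, cfg,
                      schedule = as.Date("2017-06-19"),
                      include_assessments = FALSE)
  # only 1 day ago (June 18 = study day 3) compliant
  expect_equal(r$score, 4)
  expect_false(r$assessment_flag)
})

test_that("the default schedule queries twice a week inside the study", {
  sched <- monitoring_schedule(as.Date("2017-06-05"), as.Date("2017-07-02"))
  expect_true(all(weekdays(sched) %in% c("Monday", "Thursday")))
  expect_equal(length(sched), 8)
})
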