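test_that("a fixed seed reproduces the bundle exactly", {
  a <- simulate_hd_profile(seed = 5, n_patients = 4, study_length_days = 30)
  b <- simulate_hd_profile(seed = 5, n_patients = 4, study_length_days = 30)
  expect_identical(a$roster, b$roster)
  expect_identical(a$events, b$events)
  expect_identical(a$streaming, b$streaming)
  expect_identical(a$charging, b$charging)
  c <- simulate_hd_profile(seed = 6, n_patients = 4, study_length_days = 30)
  expect_false(identical(a$events, c$events))
})

test_that("study profiles carry their protocol metric sets and sizes", {
  pd <- simulation_params("PD-study")
  hd <- simulation_params("HD-study")
  expect_equal(pd$n_patients, 51L)
  expect_equal(hd$n_patients, 17L)
  expect_false("assessment" %in% pd$metrics)
  expect_true("assessment" %in% hd$metrics)

  bp <- simulate_pd_profile(seed = 2, n_patients = 3, study_length_days = 15)
  bh <- simulate_hd_profile(seed = 2, n_patients = 3, study_length_days = 15)
  expect_false(any(bp$events$event_kind == "assessment"))
  expect_true(any(bh$events$event_kind == "assessment"))
})

test_that("degenerate parameters give a clean cohort at the configured baselines", {
  p <- simulation_params("PD-study", n_patients = 30,
                         study_length_days = 40, seed = 8,
                         dropout_hazard = 0,
                         metric_loadings = c(medication = 0, symptom = 0,
                                             streaming = 0),
                         idiosyncratic_sd = 0, record_loss = 0,
                         decline_fractions = c(medication = 0, symptom = 0,
                                               streaming = 0),
                         settling_start = c(medication = 1, symptom = 1,
                                            streaming = 1))
  b <- simulate_cohort(p)
  expect_true(all(is.na(b$roster$termination_date)))
  d <- daily_metrics(b)
  # post-settling-window cohort means sit at the configured baselines
  late <- d[d$study_day >= 14, ]
  expect_equal(mean(late$medication_reports), 5.82, tolerance = 0.05)
  expect_equal(mean(late$symptom_events), 1.61, tolerance = 0.05)
  expect_equal(mean(late$streaming_hours), 13.32, tolerance = 0.05)
})

test_that("parameter validation rejects infeasible settings", {
  expect_error(simulation_params("PD-study", decline_fractions =
                                   c(medication = 1.2, symptom = 0.4,
                                     streaming = 0.5)), "decline")
  expect_error(simulation_params("PD-study", dropout_hazard = 1), "hazard")
  expect_error(simulation_params("PD-study", baseline_rates =
                                   c(medication = -1, symptom = 1,
                                     streaming = 10)), "nonnegative")
})

test_that("HD medication events respect the two-dose protocol windows", {
  b <- simulate_hd_profile(seed = 12, n_patients = 17)
  med <- b$events[b$events$event_kind == "medication", ]
  hr <- as.numeric(format(med$timestamp, "%H", tz = "UTC")) +
    as.numeric(format(med$timestamp, "%M", tz = "UTC")) / 60
  in_morning <- hr >= 7 & hr <= 12
  # evening doses are offset 7-10 h from the morning window: 14:00-22:00
  in_evening <- hr >= 14 & hr <= 22
  expect_gt(mean(in_morning | in_evening), 0.95)
  # roughly two scheduled doses: no day exceeds 2 reports
  d <- daily_metrics(b)
  expect_lte(max(d$medication_reports), 2)
})

test_that("simulated dropout matches the roster and the n_active series", {
  b <- simulate_pd_profile(seed = 13, n_patients = 20,
                           study_length_days = 60,
                           dropout_hazard = 0.02)
  d <- daily_metrics(b)
  s <- cohort_mean(d, b$roster, "streaming_hours", b$config)
  # censoring consistency: n_active on day k counts patients whose active
  # span covers day k, straight from the roster
  expected_active <- vapply(s$study_day, function(k) {
    term <- b$roster$termination_date
    active_days <- ifelse(is.na(term), 60, term - b$roster$enrollment_date)
    sum(active_days >= k)
  }, numeric(1))
  expect_equal(s$n_active, as.integer(expected_active))
  expect_true(any(!is.na(b$roster$termination_date)))
})

test_that("wear timing is noon-peaked with reminder-anchored events", {
  b <- simulate_hd_profile(seed = 14, n_patients = 17)
  ps <- hourly_profile(b, "streaming_hours", "count")
  expect_true((which.max(ps$value) - 1) %in% 11:13)
  # HD symptom reports cluster near the 12:00 reminder
  sym <- hourly_profile(b, "symptom_events", "fraction")
  expect_gt(sum(sym$value[sym$hour %in% 10:14]), 0.9)
  # assessments near the alternating 9:00 / 18:00 reminders
  ass <- hourly_profile(b, "assessments", "fraction")
  expect_gt(sum(ass$value[ass$hour %in% c(8:10, 17:19)]), 0.9)
})
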