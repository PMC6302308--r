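#' @title Hourly profiles, weekend effects and per-patient correlations
#' @description Clock-hour engagement profiles, the weekend/holiday
#'   comparison, and Spearman rank correlations between per-patient mean
#'   compliance levels (cross-metric) and against demographic covariates.
#' @name patterns
NULL

#' Clock-hour profile of one compliance metric
#'
#' Event metrics are binned by the local clock hour of each event;
#' streaming is binned by the summed hour-validity contribution in each
#' clock hour, so the profile reflects validated streaming time rather
#' than raw record presence.
#'
#' @param bundle A \code{cohort_bundle}.
#' @param metric One of \code{"medication_reports"}, \code{"symptom_events"},
#'   \code{"assessments"}, \code{"streaming_hours"}.
#' @param normalization \code{"count"} (raw totals), \code{"fraction"}
#'   (bins sum to 1), or \code{"mean_per_active_day"} (per active
#'   patient-day).
#' @param config A \code{study_config}.
#' @return Data frame of class \code{hourly_profile}: \code{metric, hour,
#'   value, normalization} with 24 rows.
#' @export
hourly_profile <- function(bundle, metric,
                           normalization = c("count", "fraction",
                                             "mean_per_active_day"),
                           config = bundle$config) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  normalization <- match.arg(normalization)
  kind <- switch(metric,
                 medication_reports = "medication",
                 symptom_events = "symptom",
                 assessments = "assessment",
                 streaming_hours = "streaming",
                 stop("unknown metric '", metric, "'", call. = FALSE))
  bins <- numeric(24)
  if (kind == "streaming") {
    s <- bundle$streaming
    if (nrow(s)) {
      cf <- charging_hour_fractions(bundle$charging)
      m <- merge(s, cf, by = c("patient_id", "hour_start"), all.x = TRUE)
      m$charging_fraction[is.na(m$charging_fraction)] <- 0
      contrib <- hour_validity(m$record_count, m$charging_fraction, config)
      hr <- as.integer(format(m$hour_start, "%H", tz = "UTC"))
      tb <- tapply(contrib, factor(hr, levels = 0:23), sum)
      bins <- as.numeric(ifelse(is.na(tb), 0, tb))
    }
  } else {
    ev <- bundle$events[bundle$events$event_kind == kind, , drop = FALSE]
    if (kind == "assessment") {
      ses <- assessment_sessions(bundle$events, config)
      hr <- as.integer(format(ses$session_start, "%H", tz = "UTC"))
    } else {
      hr <- as.integer(format(ev$timestamp, "%H", tz = "UTC"))
    }
    bins <- as.numeric(table(factor(hr, levels = 0:23)))
  }
  total <- sum(bins)
  value <- switch(normalization,
                  count = bins,
                  fraction = if (total > 0) bins / total else bins,
                  mean_per_active_day = bins /
                    nrow(patient_days(bundle$roster, config)))
  out <- data.frame(metric = metric, hour = 0:23, value = value,
                    normalization = normalization, stringsAsFactors = FALSE)
  class(out) <- unique(c("hourly_profile", class(out)))
  out
}

#' Weekend/holiday versus weekday comparison
#'
#' Labels each patient-day as weekend (Saturday, Sunday, or a supplied
#' holiday) or weekday, and compares the daily metric values between the
#' two groups with a two-sample, two-tailed Student's t-test. The unit of
#' analysis is the patient-day, treated as independent (a simplification;
#' set \code{aggregate_patients = TRUE} to compare per-patient means
#' instead).
#'
#' @param daily A \code{daily_metrics} table.
#' @param metric Metric column to compare.
#' @param holidays Optional vector of holiday dates counted with weekends.
#' @param aggregate_patients If \code{TRUE}, average within patient before
#'   testing (patient becomes the unit of analysis, paired by patient).
#' @return List of class \code{weekend_test}: group means and sizes, the t
#'   statistic, degrees of freedom and the two-sided p-value.
#' @export
weekend_comparison <- function(daily, metric, holidays = as.Date(character(0)),
                               aggregate_patients = FALSE) {
  if (!metric %in% names(daily))
    stop("unknown metric '", metric, "'", call. = FALSE)
  wk <- weekdays(daily$date) %in% c("Saturday", "Sunday") |
    daily$date %in% holidays
  if (!any(wk) || all(wk))
    stop("weekend comparison undefined: one group is empty", call. = FALSE)
  if (aggregate_patients) {
    agg <- stats::aggregate(daily[[metric]],
                            by = list(patient_id = daily$patient_id,
                                      weekend = wk), FUN = mean)
    x <- agg$x[agg$weekend]
    y <- agg$x[!agg$weekend]
    tt <- stats::t.test(x, y, paired = FALSE, var.equal = TRUE)
  } else {
    x <- daily[[metric]][wk]
    y <- daily[[metric]][!wk]
    tt <- stats::t.test(x, y, var.equal = TRUE)
  }
  structure(list(metric = metric,
                 mean_weekday = mean(y), mean_weekend = mean(x),
                 n_weekday = length(y), n_weekend = length(x),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value),
            class = "weekend_test")
}

#' @export
print.weekend_test <- function(x, ...) {
  cat(sprintf("Weekend/holiday comparison of %s\n", x$metric))
  cat(sprintf("  weekday mean %.3f (n=%d), weekend mean %.3f (n=%d)\n",
              x$mean_weekday, x$n_weekday, x$mean_weekend, x$n_weekend))
  cat(sprintf("  t = %.3f, df = %.0f, two-sided p = %.3f\n", x$t, x$df, x$p))
  invisible(x)
}

#' Per-patient mean compliance summaries
#'
#' Averages each metric over a patient's enrolled, uncensored days (the
#' zero-filled rows of the daily table) and joins the covariates used for
#' correlation analysis.
#'
#' @param daily A \code{daily_metrics} table.
#' @param roster A validated roster.
#' @param metrics Metric columns to summarize.
#' @return Data frame with one row per patient: the per-metric means plus
#'   \code{age_years}, \code{gender} and \code{baseline_severity}.
#' @export
patient_summary <- function(daily, roster, metrics = metric_names(daily)) {
  agg <- stats::aggregate(daily[, metrics, drop = FALSE],
                          by = list(patient_id = daily$patient_id), FUN = mean)
  out <- merge(agg,
               roster[, c("patient_id", "age_years", "gender",
                          "baseline_severity")],
               by = "patient_id")
  out[order(out$patient_id), , drop = FALSE]
}

# Spearman correlation with average-rank ties; NA when either side is
# constant or fewer than 3 complete pairs exist.
spearman_or_na <- function(x, y, min_n = 3L) {
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < min_n) return(list(r = NA_real_, n = sum(ok)))
  x <- x[ok]; y <- y[ok]
  if (length(unique(x)) < 2L || length(unique(y)) < 2L)
    return(list(r = NA_real_, n = length(x)))
  list(r = stats::cor(x, y, method = "spearman"), n = length(x))
}

#' Pairwise Spearman correlations between per-patient metric means
#'
#' Quantifies whether patients are consistently high- or low-compliant
#' across protocol requirements: each entry is the Spearman rank
#' correlation (average ranks on ties) between two metrics' per-patient
#' means. Pairs with fewer than 3 complete patients, or a constant metric,
#' are \code{NA}.
#'
#' @param summaries Output of \code{\link{patient_summary}}.
#' @param metrics Metric columns to correlate.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
pairwise_metric_correlation <- function(summaries,
                                        metrics = intersect(
                                          c("medication_reports",
                                            "symptom_events", "assessments",
                                            "streaming_hours"),
                                          names(summaries))) {
  k <- length(metrics)
  out <- diag(1, k)
  dimnames(out) <- list(metrics, metrics)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    r <- spearman_or_na(summaries[[metrics[i]]], summaries[[metrics[j]]])$r
    out[i, j] <- out[j, i] <- r
  }
  out
}

#' Spearman correlation of each metric with a demographic covariate
#'
#' @param summaries Output of \code{\link{patient_summary}}.
#' @param covariate \code{"age_years"} or \code{"baseline_severity"}.
#' @param metrics Metric columns to correlate.
#' @return Data frame \code{metric, covariate, r, n}.
#' @export
covariate_correlation <- function(summaries,
                                  covariate = c("age_years",
                                                "baseline_severity"),
                                  metrics = intersect(
                                    c("medication_reports", "symptom_events",
                                      "assessments", "streaming_hours"),
                                    names(summaries))) {
  covariate <- match.arg(covariate)
  rows <- lapply(metrics, function(m) {
    s <- spearman_or_na(summaries[[m]], summaries[[covariate]])
    data.frame(metric = m, covariate = covariate, r = s$r, n = s$n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
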