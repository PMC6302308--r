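#' Run the full compliance analysis on a cohort bundle
#'
#' The package's central entry point: from raw event logs it computes the
#' per patient-day metrics table, the smoothed and censored cohort curves
#' with burn-in-to-end change summaries, the twice-weekly monitoring flags,
#' hourly engagement profiles, the weekend/holiday comparison for
#' streaming, and the per-patient cross-metric and covariate Spearman
#' correlations.
#'
#' @param bundle A \code{cohort_bundle} (real or simulated).
#' @param config A \code{study_config}; defaults to the bundle's own.
#' @param holidays Optional holiday dates pooled with weekends.
#' @return An object of class \code{compliance_analysis}: a list with
#'   elements \code{daily}, \code{series}, \code{changes},
#'   \code{monitoring}, \code{hourly}, \code{weekend},
#'   \code{patient_summaries}, \code{metric_correlations},
#'   \code{covariate_correlations}, \code{roster} and \code{config}.
#' @examples
#' fit <- compliance_analysis(simulate_hd_profile(seed = 3, n_patients = 6,
#'                                                study_length_days = 40))
#' fit$changes
#' @export
compliance_analysis <- function(bundle, config = bundle$config,
                                holidays = as.Date(character(0))) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  daily <- daily_metrics(bundle, config)
  metrics <- metric_names(daily)
  long <- longitudinal_summary(daily, bundle$roster, config, metrics)
  str_daily <- daily[, c("patient_id", "study_day", "date",
                         "streaming_hours", "waking_streaming_hours")]
  monitoring <- run_monitoring(str_daily, bundle$events, bundle$roster,
                               config)
  hourly <- do.call(rbind, lapply(metrics, function(m)
    hourly_profile(bundle, m, "count", config)))
  weekend <- weekend_comparison(daily, "streaming_hours", holidays)
  ps <- patient_summary(daily, bundle$roster, metrics)
  structure(list(daily = daily, series = long$series,
                 changes = long$changes, monitoring = monitoring,
                 hourly = hourly, weekend = weekend,
                 patient_summaries = ps,
                 metric_correlations = pairwise_metric_correlation(ps, metrics),
                 covariate_correlations = rbind(
                   covariate_correlation(ps, "age_years", metrics),
                   covariate_correlation(ps, "baseline_severity", metrics)),
                 roster = bundle$roster, config = config),
            class = "compliance_analysis")
}

#' @export
print.compliance_analysis <- function(x, ...) {
  cat(sprintf("Compliance analysis: %d patients (%s), %d completed\n",
              nrow(x$roster), paste(unique(x$roster$study), collapse = ", "),
              sum(is.na(x$roster$termination_date))))
  cat(sprintf("Change from day %d to day %d (smoothed):\n",
              x$changes$start_day[1], x$changes$end_day[1]))
  for (i in seq_len(nrow(x$changes)))
    cat(sprintf("  %-20s %6.2f -> %6.2f  (%+.1f%% decline, study mean %.2f)\n",
                x$changes$metric[i], x$changes$start_value[i],
                x$changes$end_value[i], x$changes$percent_change[i],
                x$changes$study_mean[i]))
  cat(sprintf("Monitoring: %d/%d queries recommend contact\n",
              sum(x$monitoring$contact_recommended), nrow(x$monitoring)))
  cat(sprintf("Weekend vs weekday streaming: p = %.2f\n", x$weekend$p))
  invisible(x)
}

#' @export
summary.compliance_analysis <- function(object, ...) {
  cat("Cohort change summaries:\n")
  print(object$changes, digits = 4)
  cat("\nPairwise Spearman correlations of per-patient means:\n")
  print(round(object$metric_correlations, 2))
  cat("\nCovariate correlations:\n")
  print(object$covariate_correlations, digits = 2)
  invisible(object)
}

#' Plot smoothed cohort compliance curves
#'
#' One panel per metric: the smoothed cohort mean by study day, with
#' vertical censoring ticks (and remaining-patient counts) where patients
#' drop out.
#'
#' @param x A \code{compliance_analysis}.
#' @param metrics Metrics to draw; defaults to all.
#' @param ... Passed to \code{plot.default}.
#' @export
plot.compliance_analysis <- function(x, metrics = unique(x$series$metric),
                                     ...) {
  old <- graphics::par(mfrow = c(length(metrics), 1),
                       mar = c(3.5, 4, 1.5, 1))
  on.exit(graphics::par(old))
  for (m in metrics) {
    s <- x$series[x$series$metric == m, ]
    graphics::plot(s$study_day, s$smoothed_value, type = "l", lwd = 2,
         xlab = "study day", ylab = m, main = m, ...)
    drops <- s$study_day[which(diff(s$n_active) < 0) + 1L]
    drops <- drops[seq(1, length(drops), length.out = min(8, length(drops)))]
    for (d in drops) {
      graphics::abline(v = d, col = "grey30")
      graphics::mtext(s$n_active[s$study_day == d], side = 3, at = d,
                      cex = 0.6)
    }
  }
  invisible(x)
}
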