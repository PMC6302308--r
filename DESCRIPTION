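Package: wearcompliance
Title: Compliance Metrics for Remote Digital Trials with Wearables and
    Smartphone Apps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes remote-protocol compliance metrics for six-month
    digital clinical trials that combine a data-streaming smartwatch with a
    smartphone application: daily accelerometer streaming hours validated by
    an hourly record-count rule with charging-time exclusion, app-based
    medication and symptom reporting counts, and structured home-assessment
    performances. Aggregates per-patient daily metrics into smoothed,
    dropout-censored cohort curves with percent-change summaries, implements
    a weighted three-day streaming score with intervention flags for
    twice-weekly compliance monitoring, derives hourly and weekday
    engagement profiles, and estimates per-patient cross-metric and
    covariate Spearman correlations. Includes a synthetic-cohort event-log
    simulator so the full pipeline can be exercised and validated without
    access to raw trial data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
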