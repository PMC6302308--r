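# wearcompliance

Compliance analysis for remote digital clinical trials that pair a
data-streaming smartwatch with a smartphone application.

Long remote studies of movement disorders (Parkinson's disease,
Huntington disease) ask patients to wear a wrist accelerometer all day,
report every medication intake (or skip) in an app, report symptoms
daily, and — in some protocols — perform short structured motor
assessments at home every other day. Whether patients actually keep
doing all of this for six months is the central operational question for
anyone designing such a trial. This package implements the full
analysis pipeline for that question, working from raw event logs to
cohort-level answers, for statisticians and trial operations teams.

## What it computes

Four remote-compliance metrics per patient-day:

* **Streaming hours** — a clock hour of accelerometer streaming counts
  only if it carries at least 90% of the records expected at the device
  sampling rate (50 Hz → 162,000 records/h); charging time is excluded
  by prorating both the expectation and the hour's credit. Daily value:
  sum of hour contributions, with a waking-window (09:00–21:00)
  restriction kept alongside.
* **Medication reports** — app-based intake reports; a logged *skip* is
  engagement and counts like a *take*.
* **Symptom events** — one count per report interaction, whether it
  lists one symptom or eight.
* **Assessment performances** — home-assessment task events (stand 30 s,
  sit 2 min) grouped into one performance per 30-minute session.

On top of these:

* **Longitudinal cohort curves** — per study-day cross-patient means
  with dropout censoring (patients leave numerator and denominator from
  their termination date), smoothed with a 7-day trailing moving
  average; percent-change summaries from the day-14 burn-in to the last
  active day, `100 (x₁₄ − x_T) / x₁₄`, decline positive.
* **Monitoring flags** — the twice-weekly intervention rule: a day is
  compliant when waking-window streaming ≥ 0.9 × 12 h = 10.8 h; the
  last three days score 4/2/1 points (1/2/3 days ago) and a score < 3
  flags the patient, as does < 3 assessment performances in the trailing
  8 days.
* **Patterns** — clock-hour profiles per metric, a two-tailed Student's
  t-test of weekend/holiday vs weekday compliance, and Spearman rank
  correlations of per-patient mean compliance across metric pairs and
  against age / baseline severity.
* **A synthetic-cohort simulator** — generates rosters, event logs,
  hourly streaming counts and charging intervals with the structure the
  analysis assumes (shared per-patient compliance propensity, linear
  decline after day 14, first-week settling, noon-peaked wear,
  reminder-anchored event times, geometric dropout), so the entire
  pipeline is testable without access to any trial's raw data.

## Worked example

```r
library(wearcompliance)

b <- simulate_hd_profile(seed = 11)   # 17 patients, 182 days, 4 metrics
fit <- compliance_analysis(b)
print(fit)
```

```
Compliance analysis: 17 patients (HD-study), 7 completed
Change from day 14 to day 182 (smoothed):
  medication_reports     1.69 ->   1.78  (-5.0% decline, study mean 1.68)
  symptom_events         0.66 ->   0.59  (+10.7% decline, study mean 0.62)
  assessments            0.45 ->   0.31  (+32.2% decline, study mean 0.36)
  streaming_hours       10.81 ->   7.10  (+34.3% decline, study mean 8.51)
Monitoring: 499/600 queries recommend contact
Weekend vs weekday streaming: p = 0.99
```

Reading the output: each line is one metric's smoothed cohort mean at
study day 14 and at the last day with any active patient, the percent
change between them (negative = the cohort *improved*), and the mean of
the smoothed curve over that span. Medication reporting stays near the
protocol's 2 daily doses while streaming hours erode; with 17 patients
the stochastic run-to-run spread around the generative decline
parameters is substantial, which is exactly what the small-cohort
profile is meant to exhibit. The monitoring line counts scheduled
twice-weekly checks whose streaming score or assessment count fell
below threshold. `summary(fit)` adds the cross-metric Spearman matrix
(here 0.56–0.80: patients are consistently high- or low-compliant
across requirements) and covariate correlations; `plot(fit)` draws the
smoothed curves with censoring ticks.

The same interface runs on real data laid out as CSV tables
(`roster.csv`, `events.csv`, `streaming_hours.csv` or
`streaming_raw.csv`, `charging.csv` — see `?read_bundle`):

```r
bundle <- read_bundle("inputs/")
fit <- compliance_analysis(bundle)
```

or from a shell via the bundled driver:

```sh
Rscript $(Rscript -e 'cat(system.file("scripts/compliance-cli.R",
                                      package = "wearcompliance"))') \
  simulate --profile pd --seed 1 --out inputs/
# ... then
  compute --inputs inputs/ --out results/
```

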