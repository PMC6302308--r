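---
title: "Methods: remote-trial compliance metrics, monitoring and simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: remote-trial compliance metrics, monitoring and simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's account of its methods: the compliance
metrics it computes, the monitoring rule, the longitudinal aggregation,
the correlation analyses, and the generative model behind the synthetic
cohorts — together with the numerical and design choices made where the
underlying protocol descriptions leave room.

```{r setup}
library(wearcompliance)
```

## The setting and the unit of analysis

A remote digital trial asks each patient to stream wrist-accelerometer
data continuously, report medication intakes and symptoms through a
smartphone app, and (in the Huntington-type protocol) perform bi-daily
structured motor assessments at home. Compliance here means
*participation level*: a continuous per-day quantity, not the binary
"met protocol" indicator. Everything in the package reduces to rows of
one table — patient, study day, and the four metric values — which is
then aggregated, scored or correlated.

All timestamps are naive local device time. The analyses that matter
(clock-hour profiles, the waking window, reminder anchoring) are
local-clock phenomena, so no timezone or DST arithmetic is performed;
internally a fixed-offset container (UTC) holds the values so that hour
arithmetic never crosses a DST boundary.

## Streaming hours: the hour-validity rule

An hour of streaming counts only if it is reasonably complete. With
sampling rate $r$ (default 50 Hz) and a completeness fraction $q$
(default 0.9), an uncharged hour is valid when its record count reaches
$q \cdot 3600 r$ — 162,000 records at the defaults, and the boundary is
inclusive: 162,000 is valid, 161,999 is not.

Charging must be excluded, and the protocol text does not say at what
granularity. The package prorates within the hour: if merged charging
intervals cover fraction $c$ of the hour, the expectation becomes
$3600 r (1-c)$, the validity test is applied against $q$ of that, and a
valid hour contributes $1-c$ hours (an hour fully inside a charging
interval contributes 0). Proration preserves the completeness intent at
sub-hour granularity: half an hour of perfect streaming around a
half-hour charge counts as half an hour, rather than being discarded.

One consequence is worth stating plainly. For a *fixed* record count,
adding charging time lowers the prorated expectation and can therefore
turn an invalid hour valid — extra charging "explains away" missing
records. This is semantically right (those records could never have
been streamed) but it means exclusion is not monotone against frozen
counts. In the physically consistent regime — record counts co-vary
with charging because streaming stops while the watch charges — adding
a charging interval can only remove streaming hours, and that is the
regime in which the test suite asserts monotonicity; the frozen-count
regime is instead pinned by a per-second brute-force oracle.

Days are local calendar days; study day 1 is the enrollment date.
Every enrolled, uncensored patient-day appears in the daily table, with
explicit zeros on days without data — zero-filling is what makes cohort
means and censoring semantics well defined downstream.

## App-engagement metrics

*Medication*: `take` and `skip` both count as reports — the metric
measures engagement with the reporting task, not drug adherence.
*Symptoms*: one report interaction is one event regardless of how many
of the eight symptom labels it carries (or whether it is a single
chorea-severity value). *Assessments*: protocols count performances,
not task events; all assessment events from one patient within a
30-minute session window (`assessment_session_minutes`, configurable)
form one performance, so a stand-30s and a sit-2min logged at the same
sitting count once. Bi-daily tallies use non-overlapping two-day blocks
anchored at each patient's enrollment; monitoring uses trailing windows
ending at the query day.

## Longitudinal aggregation

Cohort curves are computed per study day as the mean over patients
*active* that day — a patient is censored from their termination date
onward, leaving both numerator and denominator, and `n_active` records
the remaining count. Means are computed first and smoothed second
(aggregate-then-smooth), with a 7-day *trailing* moving average that
shortens at the series start. Trailing was chosen over centered because
it matches real-time monitoring use and never looks ahead; the choice
is visible mainly in the first week and at the series end.

Change is quantified from a burn-in day (default 14) because the first
days of enrollment behave differently from the rest of the study; the
summary is

$$\text{percent change} = 100\,\frac{x_{14} - x_{T}}{x_{14}},$$

decline positive, where $T$ is the last study day with any active
patient, capped at the protocol length (182 days). The study mean
averages the smoothed curve over $[14, T]$. Feeding published day-14 /
final-day endpoint pairs through this computation reproduces the
corresponding published percentages at printed precision for six of the
seven metric series; the bi-daily assessment endpoints 0.95 → 0.66
yield 30.53% from the rounded values themselves, and the package
reports what it computes rather than matching a figure that its own
inputs cannot produce.

## The monitoring rule

The intervention rule is evaluated on a twice-weekly schedule
(defaulting to Mondays and Thursdays; the protocol names no days). A
*compliant day* streams at least $q$ of the waking window —
$0.9 \times 12\,\text{h} = 10.8\,\text{h}$ between 09:00 and 21:00,
boundary inclusive. The three most recent *calendar* days before the
query date are weighted 4 (yesterday), 2, 1; the worked description of
the rule ("1 point for three days ago ...") supports calendar-day lags
rather than the three most recent compliant days. Scores below 3 raise
the streaming flag; fewer than 3 assessment performances in the
trailing 8 days raise the assessment flag; either flag recommends
contact. Days before enrollment count as non-compliant, so early
queries score conservatively over the days available. The score space
is tiny (2³ patterns), and the tests enumerate it exhaustively.

## Patterns and correlations

Hourly profiles bin events by local clock hour; streaming is binned by
summed hour-validity contribution, so the profile shows validated
streaming time. The weekend comparison is a two-sample, two-tailed
Student's t-test (equal variances) on daily values labelled weekend
(Saturday/Sunday plus a user-supplied holiday list — holiday calendars
are site-specific and not built in). The unit of analysis is the
patient-day, treated as independent; this matches how such comparisons
are usually reported but understates within-patient correlation, so a
patient-level aggregation option (`aggregate_patients = TRUE`) is
provided.

Per-patient summaries average each metric over the patient's enrolled,
uncensored days. Cross-metric and covariate association uses Spearman
rank correlation with average ranks on ties (the standard choice);
pairs with fewer than three complete patients or a constant metric are
reported as `NA` rather than a number.

## The synthetic cohort generator

No raw data from the motivating studies are public, so the simulator
is the package's test bed. Its defaults encode the two study profiles:

* Parkinson's profile: 51 patients, metrics medication / symptoms /
  streaming, day-14 cohort baselines 5.82 reports, 1.61 events,
  13.32 h, total declines 34.2% / 43.5% / 52.7%.
* Huntington profile: 17 patients, adds bi-daily assessments
  (0.95 performances per two days, declining 30.37%), baselines 1.75 /
  0.72 / 10.51 h with declines 2.86% / −1.39% / 20.36%, a fixed
  two-dose regimen (morning dose 07:00–12:00, second dose 7–10 h
  later), a 12:00 symptom reminder, and 09:00/18:00 alternating
  assessment reminders.

The generative model: patient $i$ draws a latent propensity
$\theta_i \sim N(0, 1)$; metric $m$ applies multiplier
$\exp(\ell_m \theta_i + \varepsilon_{im})$ with loading
$\ell_m = 0.35$ and idiosyncratic $\varepsilon_{im} \sim N(0, 0.29)$.
These values were calibrated analytically to the target cross-metric
rank correlation of about 0.55: the latent Pearson correlation is
$\ell^2/(\ell^2 + \tau^2) \approx 0.59$, which the Gaussian rank
conversion $(6/\pi)\arcsin(\rho/2)$ and day-level sampling noise bring
to ≈ 0.55 in per-patient means. For the Huntington profile, age and
baseline severity additionally load on the streaming propensity
(0.253 and 0.268), chosen the same way for rank correlations near
0.46 / 0.49.

Daily intensity is baseline × decline × settling × multiplier. Decline
is linear from day 14 to study end (an exponential option exists for
rapid-drop scenarios); multipliers are normalized so that the *capped*
cohort-mean intensity equals the baseline at day 14 — capping matters
because intensities saturate at physical limits (at most 23 wearable
hours once a daily charging session is taken out; at most one report
per scheduled dose or daily reminder), and normalizing on the uncapped
scale would bias cohort baselines low.

Settling: early-study behaviour differs from the rest (low streaming
and symptom reporting, elevated assessments), and the simulator applies
a linear settling ramp over days 1–7. Confining the ramp to the first
week — rather than running it to day 13 — is deliberate: the day-14
*smoothed* value averages days 8–14, and a ramp still active there
would structurally depress the day-14 baseline that the generator is
defined to hit.

Wear is realized as one contiguous whole-hour block per day, with
duration drawn around the day's target hours (SD 1.3 h) and center
around 13:00 (SD 1 h) — producing the observed shape of wear time:
rising through the morning, peaking near noon, dropping sharply around
20:00. Worn hours draw record counts binomially with 2% sample loss;
a daily charging session (≈ 1.5 h around 22:30) is carved out, and
counts in overlapped hours are thinned accordingly. Event clock times
are reminder-anchored with Gaussian jitter; free-form Parkinson symptom
reporting uses a morning-weighted mixture instead. Dropout is a
per-day geometric hazard, calibrated so expected completer counts match
the profiles' published 36/51 and 9/17 over 182 days (hazards 0.00192
and 0.00351). A single seed drives every draw, so bundles are
byte-reproducible.

What the simulator does *not* emulate — and hence what passing
recovery tests do not show about real data: no within-patient
day-to-day autocorrelation by default (an AR(1) day effect is exposed
but off), no weekend structure (the generator is null by construction,
which is what the type-I-error test needs), no missing-not-at-random
dropout (hazard is independent of propensity), no clock drift or
timezone travel, no double-tap deduplication beyond assessment session
grouping, and record counts rather than accelerometer waveforms.

## Problem sizes and numerical choices in the tests

The suite runs full-size cohorts where the claim is about cohort
recovery (51 patients × 182 days; a 17-patient Huntington run for the
protocol-window check) and small cohorts (3–6 patients, 15–60 days)
everywhere the claim is structural. Oracle comparisons use 200
randomized 1–3-day instances against a per-second brute-force
simulation of streaming and charging state, with whole-second charging
endpoints so the two routes are exactly comparable; the weekend test's
type-I error uses 1000 replicates of a 5-patient, 28-day null. Recovery
tolerances are ±10% on day-14 baselines, ±10 percentage points on
declines, and [0.35, 0.75] on pairwise Spearman values at $n = 51$
(sampling SD ≈ 0.09 around the induced ≈ 0.55). Equality boundaries
(162,000 records; 10.8 waking hours; score threshold 3) are tested
inclusively on the compliant side and exclusively one unit below.

## Known limitations

* Streaming measures *streaming*, not wearing: a watch left on a table,
  powered and not charging, counts. Non-wear detection from signal
  magnitude is out of scope by design.
* The percent-change summary is descriptive; no inferential model of
  decline (survival, mixed models) is fitted.
* The weekend t-test's patient-day independence assumption inflates
  effective sample size on real data; use the patient-level option when
  that matters.
* Monitoring flags are advisory output; no contact workflow or
  unscheduled-call heuristic is modelled — the generic
  threshold-on-trailing-mean hook for the latter is deliberately left
  disabled because no numeric rule is defined for it.
* With 17 patients, small-cohort runs are noisy: single-seed declines
  can sit far from the generative values, which is a property of the
  design size, not of the estimator.
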