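---
title: "Validating self-reported physical activity against accelerometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating self-reported physical activity against accelerometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paconcord)
```

`paconcord` implements a complete convergent-validity analysis for
physical-activity (PA) measurement: device-side processing of
minute-epoch accelerometer counts, scoring of four self-report
instruments into commensurate minutes/week, and an agreement battery
comparing each instrument to the device. Because raw cohorts of this
kind are rarely shareable, the package also ships a seeded synthetic
cohort generator with known ground truth; every pipeline stage is
validated by parameter recovery against that truth. This vignette
documents the model, the tunable parameters, the numerical choices, and
what the synthetic validation does and does not establish.

## Device-side model

The device atom is a participant-day of 1440 one-minute epochs of
activity counts (cpm). Processing has three stages:

1. **Nonwear screening.** Nonwear is any maximal window of at least
   `zero_run_min = 60` minutes of zero counts, tolerating interruptions
   of at most `allowance_max_epochs = 2` consecutive epochs, each at or
   below `allowance_cpm_max = 100` cpm. An epoch above 100 cpm, or a
   third consecutive nonzero epoch, terminates the window, and a window
   always begins and ends on a zero epoch — so trailing interruptions
   that never return to zero are not absorbed. This is the standard
   Troiano-style reading of the "60 min of zeros with a 1–2 min
   allowance" rule; the allowance minutes inside a qualifying window
   count as nonwear. Wear time is the complement of nonwear within the
   24-hour day. Windows are detected within a single day record;
   cross-midnight stitching is deliberately not performed (day records
   are the unit of exchange, and the validity rule below operates per
   day).
2. **Intensity classification.** Each worn epoch falls in exactly one
   count band. Defaults are the Freedson adult cut points — sedentary
   ≤ 99 cpm, light 100–1951, moderate 1952–5724, vigorous ≥ 5725 —
   configurable via `freedson_cut_points()`. Consequently sedentary,
   light, moderate and vigorous minutes always partition wear minutes,
   a property the test suite asserts on random days. Nonwear is counted
   nowhere: in particular, nonwear is not sedentary time.
3. **Wear-time validity and weekly summaries.** A day is valid with
   ≥ 10 h (600 min) of wear; a participant needs ≥ 4 valid days for a
   device estimate, otherwise the estimate is missing and the
   participant drops out of device comparisons (complete-case).
   Weekly values are the mean over valid days × 7
   (`scale = "day_mean_x7"`). The ×7 scaling is a design choice: the
   source procedure states only "averaging daily estimates", but all
   instruments must share minutes/week units for the agreement
   statistics to be meaningful. A `sum_valid` alternative (plain sum
   over valid days) is provided for sensitivity analyses; note it
   conflates wear quantity with activity quantity.

## Instrument scoring

- **EMA daily diary.** Eight duration categories per intensity
  (0–9, 10–19, …, 60–69, ≥ 70 min) scored at the category mean: 4.5,
  14.5, …, 64.5 and 70 for the open-ended top category. The top
  category has no interior mean; it is scored at its lower bound 70 by
  default (`ema_midpoint_top`), a conservative choice that caps the
  diary's weekly range at 490 min per intensity. Whether the first
  option is "0" exactly or "0–9 min" is not determined by the worked
  midpoint example (which fixes only the third bin at 24.5); we use
  0–9 with midpoint 4.5 and expose the whole table as configuration.
  Weekly estimates sum answered days with **no** imputation or
  rescaling of missing days — the estimate is "time reported across
  days of observation". A `rescale_to_7_days` switch exists but
  defaults off.
- **BRFSS-style items.** Weekly minutes per intensity are usual
  duration (min/day) × frequency (times/week); MVPA is the sum and is
  missing when either intensity is missing. Frequency is not capped at
  7 (multiple sessions/day are possible responses).
- **IPAQ-style items.** Five activity items (occupational vigorous,
  occupational moderate, occupational walking, transport walking,
  transport bicycling), each days/week × hours/day × 60. All walking
  and bicycling items count as moderate; occupational vigorous is the
  only vigorous item. The "at least 10 minutes at a time" clause is
  part of the question wording, not a post-hoc filter, and no
  truncation rules (e.g. 960-min caps) are applied to reported values.
  Sitting: the weekday and weekend hours items are combined as
  (5 × weekday + 2 × weekend) × 60 min/week, i.e. a day-type-weighted
  week.
- **Screen time.** Television + computer hours/day by day type,
  collapsed as (weekday sum × 5 + weekend sum × 2) × 60. A combined
  report over 24 h/day is an impossible response and errors by default
  (`cap_at_week = TRUE` caps the week at 10080 min instead).

## Agreement battery

All comparisons are complete-case per cell: each instrument pair ×
intensity uses exactly the participants with both values present, so n
varies across cells and is always reported.

- **Spearman ρ** of midranks, p-value from
  `t = ρ √((n−2)/(1−ρ²))` on n − 2 df. The t approximation is accurate
  at the cohort sizes targeted (n of order 150–240); the test suite
  cross-checks both ρ and p against `stats::cor.test`. Family-wise
  control uses Holm's sequential step-down rule (via
  `stats::p.adjust`). The family is configurable
  (`holm_family`): the default treats each intensity row's set of
  pairwise tests as one family; `"all"` pools the whole correlation
  table. Published tables of this kind are ambiguous about the family;
  both are provided.
- **Lin's concordance.**
  `ρ_c = 2 s_xy / (s_x² + s_y² + (x̄ − ȳ)²)` with 1/n moment estimators
  (the Lin 1989 convention — at small n the 1/(n−1) variant gives
  different values, so the convention matters and is fixed).
  Precision/accuracy decomposition `ρ_c = r · C_b` with
  `C_b = 2/(v + 1/v + u²)`, `v = s_x/s_y`, `u = (x̄−ȳ)/√(s_x s_y)`.
  The 95% CI is built on the atanh (Fisher z) scale with Lin's
  asymptotic variance and back-transformed. The phrase "inverse
  hyperbolic tangent transformed estimates" in this literature is read
  here as the z-transformation of the *coefficient* for CI
  construction — atanh of raw minutes/week is undefined above 1, so a
  literal data transform is not meaningful.
- **Bland–Altman on logs.** d = log(x+δ) − log(y+δ) against
  m = (log(x+δ)+log(y+δ))/2, with limits of agreement
  mean(d) ± 1.96 sd(d). Device vigorous minutes are frequently zero, so
  a log offset is required; δ = 1 min/week by default (`ba_offset`),
  configurable, with δ = 0 allowed for strictly positive data. On the
  log scale the mean difference is interpretable as a log ratio of
  (offset-shifted) weekly minutes.

Degenerate inputs are reported as missing with a warning rather than
silently: constant vectors (undefined ρ, undefined ρ_c), r = 0
(undefined C_b), cells below n = 3. Perfect concordance (|ρ_c| = 1)
collapses the CI to a point rather than evaluating the (singular)
asymptotic variance.

## The synthetic cohort: what it emulates

`cohort_params()` defaults define the reference study conditions: 238
participants × 7 days. Per participant, an activity level multiplier is
drawn from a gamma with shape `between_participant_dispersion = 2`
(mean 1); per day, true moderate and vigorous minutes are gamma with
shape `activity_dispersion = 1.2` around means of
`mean_daily_moderate_min = 22` and `mean_daily_vigorous_min = 1.5`
times the participant level. These defaults put device weekly MVPA near
165 min/week with a strongly right-skewed distribution (median below
mean), matching the shape such cohorts show; the test suite checks that
sample skewness of weekly MVPA is positive in ≥ 95% of seeded
replicates and that the Shapiro–Wilk gate rejects normality.

Days are assembled so that the device pipeline can recover truth
*exactly*: sleep and nonwear are exact zeros (wake windows average
`wake_minutes_mean = 960` min; any trailing sleep block is ≥ 60 min so
it is detectable); planted sedentary epochs use 1–99 cpm, never 0, so
zeros are unambiguous; moderate/vigorous bouts are placed inside worn
time (uniform counts within their bands) and nonwear blocks
(Poisson rate 0.3/day, 60–180 min) never overlap them. Non-compliant
days (probability 1 − `accel_compliance_prob`, default 0.35) carry a
short worn window of 2–9 h, keeping them below the 10-h validity bar;
0.65 daily compliance makes ≈ 80% of participants meet the 4-valid-day
rule. The minute-accounting invariant — sedentary + light + moderate +
vigorous = wear, and zeros = 1440 − wear — holds on every generated
day and is asserted in tests.

Self-reports derive from the same truth: the diary reports truth +
Gaussian noise (`ema_noise_sd = 10` min), truncated at zero and binned,
and is answered with probability `ema_completion_prob = 0.929`;
BRFSS/IPAQ weekly activity is truth × `questionnaire_bias_factor = 3.8`
× a mean-1 lognormal with cv `questionnaire_noise_cv = 1.5`, decomposed
into duration × frequency (5-min grid) or days × hours (0.25-h grid)
items; sitting and screen reports scale true sedentary time by
`sitting_report_factor = 0.85` / `screen_report_factor = 0.84` (0.5-h
grids). The bias factor 3.8 makes recall-questionnaire MVPA run
several-fold above device MVPA (mean over-reporting of several hundred
min/week), while the diary's only upward pressures are zero-truncation
of noise and the 4.5-min floor of the first bin — so the qualitative
ordering "diary closest to device, questionnaires far above" is a
property of the generating mechanism, and the test suite verifies the
pipeline reproduces it in ≥ 95% of 100 seeded replicates.

In the noise-free limit (`ema_noise_sd = 0`, bias factors 1, cv 0,
completion and compliance 1) every instrument recovers planted truth up
to its documented response granularity: half a bin width per sub-top
diary day; 2.5 min × frequency for BRFSS; 7.5 min × item-days for IPAQ
activity; 105 and 210 min/week for the sitting and screen 0.5-h grids.
These bounds are asserted, not approximated, in the tests.

**What the generator does not emulate**: raw 30-Hz waveforms, triaxial
vector magnitudes or any within-band count autocorrelation (only band
membership matters downstream); seasonal or day-of-week structure;
missingness that is informative (completion and compliance are
independent of activity, whereas real non-adherence may not be);
domain-specific reporting (all instruments report on the same latent
truth, whereas real instruments cover different PA domains). Passing
recovery tests therefore demonstrates the pipeline's correctness, not
the real-world validity of any instrument.

## Numerical choices and problem sizes

- Percentiles: linear interpolation between order statistics
  (`stats::quantile` type 7); normality via `stats::shapiro.test`.
- Holm decisions use the `p ≤ α/(m−i+1)` boundary (ties at the boundary
  reject), matching `stats::p.adjust`.
- The nonwear scanner is run-length based; its correctness is
  established against two independent oracles (a per-epoch state
  machine on 1000 random 1440-epoch days, and exhaustive window
  enumeration at n ≤ 150, where it is tractable), plus a monotonicity
  property: adding counts never increases nonwear.
- CI calibration for the concordance coefficient is checked by
  simulation: 1000 bivariate-normal cohorts of n = 150 with known
  population ρ_c, requiring 93–97% coverage.
- The replicate suites use 100 full-scale (238 × 7) pipeline runs for
  the instrument-ordering property and 20–60-participant cohorts for
  unit-level recovery checks; these sizes give stable Monte-Carlo
  verdicts while keeping the default test run in the minutes range.

## Known limitations

- Weekly day-mean ×7 scaling is one defensible reading of "averaging
  daily estimates"; results in minutes/week depend on it (flagged,
  configurable).
- The Holm family definition in published correlation tables of this
  design is ambiguous; per-intensity families are the default here.
- The concordance CI is asymptotic; at cell sizes below a few dozen its
  coverage is not guaranteed by the n = 150 calibration check.
- The generator's independence assumptions (missingness, bias) are
  idealizations; parameter-recovery success does not transfer to data
  violating them.
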