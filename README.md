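# paconcord

Convergent validity of self-reported physical activity against
accelerometry.

## The problem

Self-reported physical activity (PA) is cheap to collect and rich in
context, but recall questionnaires are prone to substantial
over-reporting. Method-comparison studies therefore validate
self-report instruments against waist-worn accelerometers, comparing
minutes/week of sedentary, moderate, vigorous and moderate-to-vigorous
(MVPA) activity. `paconcord` packages that whole analysis for
epidemiologists and measurement researchers:

- **Device processing** — minute-epoch (60-s) activity-count series are
  screened for nonwear (≥ 60 consecutive minutes of zero counts, with an
  allowance for 1–2 interruption epochs of ≤ 100 cpm), classified with
  Freedson adult cut points (sedentary ≤ 99, light 100–1951, moderate
  1952–5724, vigorous ≥ 5725 cpm), filtered to valid days (≥ 10 h wear)
  and summarized weekly for participants with ≥ 4 valid days.
- **Instrument scoring** — a once-daily EMA (ecological momentary
  assessment) diary with 8 duration categories (0–9, …, 60–69, ≥ 70 min)
  scored at category midpoints (a 20–29 min response scores 24.5 min)
  and summed over answered days; BRFSS-style duration × frequency items;
  IPAQ-style occupational/transport days × hours items (walking and
  bicycling count as moderate) plus sitting items; screen-time items
  with 5/2 weekday/weekend weighting.
- **Agreement battery** — Spearman rank correlations with Holm
  step-down adjustment; Lin's concordance correlation coefficient
  `ρ_c = 2 s_xy / (s_x² + s_y² + (x̄ − ȳ)²)` with its decomposition into
  precision (Pearson *r*) and accuracy (bias correction factor
  `C_b = 2 / (v + 1/v + u²)`) and a 95% CI on the
  inverse-hyperbolic-tangent scale using Lin's asymptotic variance;
  Bland–Altman limits of agreement on log-transformed minutes. All
  comparisons are complete-case.
- **Synthetic cohort generator** — a seeded simulator of the full study
  (minute counts with sleep/nonwear zeros and planted intensity bouts,
  plus all four self-report instruments derived from the same ground
  truth with controllable bias and noise), enabling end-to-end
  parameter-recovery tests.

## Worked example

```r
library(paconcord)
cfg <- study_config(params = cohort_params(n_participants = 60, seed = 2024))
res <- run_study(cfg)

res$overreporting
#>   instrument mean_instrument mean_device overreporting_min_wk
#> 1        ema           201.3       179.6                21.69
#> 2      brfss           723.4       179.6               543.77
#> 3       ipaq           825.8       179.6               646.10

subset(res$agreement, intensity == "mvpa")
#>  intensity instrument  n   lcc ci_low ci_high pearson_r pearson_p   bcf
#>       mvpa        ema 52 0.807  0.711   0.874      0.88   5.1e-18 0.915
#>       mvpa      brfss 52 0.076  0.026   0.126      0.43   1.7e-03 0.180
#>       mvpa       ipaq 52 0.069  0.046   0.092      0.71   3.1e-09 0.097
```

Of the 60 simulated participants, 52 meet the 4-valid-day device rule
and enter the device comparisons. The recall questionnaires (BRFSS,
IPAQ) over-report MVPA by hundreds of minutes/week and show poor
concordance with the device despite non-trivial correlation — the bias
correction factor (0.18, 0.10) reveals the location/scale shift that
correlation ignores — while the daily diary stays close to the device
estimate (LCC 0.81, BCF 0.92). `res$correlations`, `res$descriptives`
and `res$bland_altman` hold the remaining report tables; with
`out_dir` set, `run_study()` writes them all as CSVs plus a JSON run
manifest, byte-identical under a fixed seed.

A thin command-line front end is available at `inst/exec/pa-concord`
(`pa-concord all --config cfg.yaml --seed 7 --out results/`), and the
CSV schemas are documented in `inst/extdata/data_dictionary.csv`.

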