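Package: paconcord
Title: Convergent Validity of Self-Reported Physical Activity Against
    Accelerometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for method-comparison studies of
    physical activity measurement. Processes minute-epoch accelerometer
    count series (Troiano-style nonwear detection, Freedson cut-point
    classification, wear-time screening, weekly summaries), scores daily
    ecological momentary assessment (EMA) diaries and BRFSS-, IPAQ- and
    screen-time-style questionnaires into commensurate minutes-per-week
    estimates, and compares instruments with an agreement battery:
    Spearman rank correlations with Holm step-down adjustment, Lin's
    concordance correlation coefficient with its precision/accuracy
    decomposition and asymptotic confidence interval, and Bland-Altman
    limits of agreement on log-transformed values. A fully synthetic
    cohort generator with known ground truth and controllable reporting
    bias supports parameter-recovery testing of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
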