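Package: afrr
Title: Atrial Fibrillation Detection from RR-Interval Heterogeneity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Beat-by-beat cardiac rhythm classification from streams of
    RR intervals, as delivered by consumer chest-strap heart-rate
    monitors. Each beat is labeled probable atrial fibrillation, normal
    rhythm, or unclassified non-AF arrhythmia from a windowed
    heterogeneity index combining RR variability (normalized RMSSD) and
    serial randomness (first-order entropy rate of ternary delta-RR
    symbols). Recording-level AF calls use an AF-burden rule (at least
    90 percent of classified duration). Includes seeded simulators for
    sinus rhythm, atrial fibrillation, atrial flutter, ectopy and sensor
    artifacts, an emulator of a paired pre/post-cardioversion validation
    study, and diagnostic-accuracy statistics (sensitivity, specificity,
    Cohen's kappa, exact binomial confidence intervals).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    e1071,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
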