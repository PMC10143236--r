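Package: wristhrv
Title: Ultra-Short-Term Heart Rate Variability Screening from Wrist-Worn PPG and Actigraphy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A 24-hour wearable heart rate variability (HRV) analysis pipeline for
    wrist photoplethysmography (PPG) and 3-axis acceleration recordings in the
    Empatica-E4 CSV dialect. Scores sleep and wake from wrist actigraphy with
    conservative rescoring rules, estimates per-minute pulse rate with a MUSIC
    pseudospectrum gated by a frequency-domain signal quality index, extracts
    validated peak-to-peak intervals for ultra-short-term HRV (RMSSD, SDNN, LF,
    HF, LF/HF, TP) under a harmonic-ratio signal quality gate, aggregates
    sleep-anchored phase features, and trains an L2-regularized logistic
    screening model with repeated stratified cross-validation. Includes a
    synthetic session generator with full ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
LinkingTo:
    Rcpp
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    signal,
    glmnet,
    pROC,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
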