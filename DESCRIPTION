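Package: hrvnorm
Title: Short-Term Heart Rate Variability Norms and Z-Score Standardization
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for building and applying age- and sex-stratified
    normative databases of short-term (five-minute) heart rate variability
    (HRV). Covers the full chain from single-lead ECG or interbeat-interval
    (IBI) recordings to standardized reports: R-peak detection, artifact
    removal by range and running-median rules, the six standard short-term
    indices (SDNN, RMSSD and Welch-estimated LF, HF, TP band powers with
    their natural-log transforms), stratified norm construction, Z-score
    conversion with deviation flags, and the cohort statistics used to
    validate a normative database against a clinical sample (pooled t,
    Pearson chi-square, ANCOVA with partial eta-squared, Pearson
    correlations). Includes an embedded reference table for Taiwanese
    adults aged 20-70 and deterministic simulators for IBI series with
    known spectral content, template ECG, stratified cohorts, and
    screening rosters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    car
Config/testthat/edition: 3
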