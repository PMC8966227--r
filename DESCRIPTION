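Package: qrsqtc
Title: QRS/QTc Ratio Analysis for Ventricular Arrhythmia Risk in
    Citalopram and Escitalopram Exposure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the QRS/QTc ratio as an electrocardiographic
    marker of ventricular arrhythmia (VT/VF, including torsade de pointes)
    risk in patients exposed to citalopram or escitalopram. Ships a
    transcribed 16-case cohort of published case reports with admission-ECG
    intervals, heart-rate correction formulas (Bazett, Fridericia,
    Framingham, Hodges), a consistency audit of reported QTc values, the
    two-group statistical pipeline used on small cohorts (population-SD
    descriptives, Shapiro-Wilk, Brown-Forsythe, pooled two-sample t-test),
    threshold-based risk classification with sensitivity/specificity sweeps,
    a synthetic-cohort generator for calibration and power studies, and a
    minimal synthetic single-lead ECG synthesiser with derivative-threshold
    QRS and tangent-method T-end delineation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    utils
Suggests:
    car,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
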