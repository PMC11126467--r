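Package: salivapk
Title: Saliva Drug Assay Validation and Non-Compartmental Pharmacokinetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy pipeline for targeted LC-MS/MS quantification of
    mycophenolic acid (MPA) and its glucuronide (MPAG) in saliva:
    calibration-curve fitting (linear and unweighted power models) with
    back-calculation, a complete bioanalytical validation battery
    (accuracy/precision, selectivity, carry-over, matrix effect, dilution
    integrity, stability, swab recovery) with ICH M10-style acceptance
    rules, non-compartmental pharmacokinetics with an enterohepatic
    secondary-peak detection rule, method-agreement statistics
    (Bland-Altman, Passing-Bablok, Pearson), and a synthetic-data
    generator that emulates instrument runs and double-peak saliva
    concentration-time profiles.
License: MIT + file LICENSE
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
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
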