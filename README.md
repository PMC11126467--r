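# salivapk

Quantification, bioanalytical validation and non-compartmental
pharmacokinetics for saliva therapeutic drug monitoring of mycophenolic
acid (MPA) and its glucuronide metabolite (MPAG), measured by targeted
LC–MS/MS.

Saliva is an attractive matrix for monitoring MPA in children — sampling
is non-invasive and saliva concentrations track the pharmacologically
active unbound drug — but it demands an assay that is accurate and
precise down to low ng/mL concentrations, and an analysis pipeline that
handles the drug's idiosyncrasies, notably the secondary concentration
peak caused by enterohepatic recirculation of MPAG back to MPA.
`salivapk` implements that pipeline end to end for people who develop or
apply such assays: analytical chemists running validation campaigns, and
pharmacokineticists analyzing the resulting concentration–time profiles.

## What it computes

* **Calibration and quantification** — unweighted linear
  (`y = aC + b`) and power (`y = αC^β`, fitted log–log) response models
  over 2–500 ng/mL; IS-ratio response for MPA, raw peak area for MPAG;
  back-calculation with BLQ/ALQ flagging and dilution correction.
* **Validation battery** with ICH M10-style acceptance rules —
  within/between-run accuracy (85–115 % of nominal; 80–120 % at the
  LLOQ) and precision (CV ≤ 15 %; ≤ 20 % at the LLOQ), selectivity
  (blank interference ≤ 20 % of the LLOQ analyte response and ≤ 5 % of
  the IS response), carry-over (strictly below the same fractions),
  matrix effect across donors, dilution integrity (|relative error| ≤ 15),
  stability per storage condition, and collection-swab recovery.
* **Non-compartmental PK** — AUC₀₋₁₂ by the linear trapezoid rule,
  C_max/t_max, and the secondary peak C_max2/t_max2 detected by a
  ≥ 20 % rise over the preceding sample (`C_i ≥ 1.2·C_{i−1}`, scanning
  strictly after t_max); cohort summaries as mean ± SD (CV%) with
  median/range for the time-to-peak parameters.
* **Method agreement** — Bland–Altman limits of agreement,
  Passing–Bablok regression implemented from the classical
  pairwise-slope algorithm (median of `(y_j−y_i)/(x_j−x_i)` shifted by
  the count of slopes < −1, rank-based CIs), Pearson correlation with
  the exact t transform, and Shapiro–Wilk normality checks.
* **Synthetic data** — double-peak saliva PK cohorts (Bateman curve plus
  a delayed enterohepatic re-absorption pulse) and complete simulated
  validation runs with controllable violations (precision faults, matrix
  suppression, degradation, carry-over), so the whole pipeline runs and
  is testable with no external data.

Everything is tidyverse-shaped: functions take data frames and return
tibbles, fitted objects support `tidy()`/`glance()`/`autoplot()`, and
results chain with the pipe.

## Worked example

Simulate a full validation campaign, run the battery, then analyze a
ten-child cohort:

```r
library(salivapk)

study  <- generate_validation_run(assay_sim_config(seed = 42))
report <- validate_run(study$run_table)
glance(report)
#> # A tibble: 7 × 4
#>   test               n_outcomes n_fail pass
#>   <chr>                   <int>  <int> <lgl>
#> 1 accuracy_precision         16      0 TRUE
#> 2 carryover                   2      0 TRUE
#> 3 dilution_integrity          2      0 TRUE
#> 4 matrix_effect              28      0 TRUE
#> 5 recovery                    4      0 TRUE
#> 6 selectivity                14      0 TRUE
#> 7 stability                  24      0 TRUE

cohort <- generate_cohort(pk_sim_config(seed = 42), n = 10)
params <- nca(cohort$profiles)
summarize_cohort(cohort$profiles, params)
#> Non-compartmental cohort summary
#> Subjects: 10 (secondary peak in 9)
#> ...
#> Parameters:
#>   MPA auc_0_t: 986.8 +/- 816.1 (CV 82.7%) [n=10]
#>   MPA cmax: 174.2 +/- 128.4 (CV 73.7%) [n=10]
#>   MPA tmax: median 1.0 (range 1.0-1.0) [n=10]
#>   MPA cmax2: 71.1 +/- 58.7 (CV 82.7%) [n=9]
#>   MPA tmax2: median 9.0 (range 9.0-9.0) [n=9]
#>   MPAG auc_0_t: 611.5 +/- 497.1 (CV 81.3%) [n=10]
#>   MPAG cmax: 102.7 +/- 74.6 (CV 72.7%) [n=10]
#>   MPAG tmax: median 2.0 (range 2.0-2.0) [n=10]
```

Every simulated subject peaks at the 1-h sample; nine of ten show a
qualifying secondary rise after the 8-h re-absorption pulse (the rise in
the tenth falls short of the 20 % rule) — the pattern expected from
enterohepatic recirculation. The validation verdicts conjoin into
`report$overall_pass`; injecting a single fault into the generator (say
`assay_sim_config(carryover_fraction = 0.3)`) fails exactly the
corresponding test.

The package also ships the published cohort-mean profiles and validation
summary tables (`reference_mean_profiles()`, `reference_qc_performance()`,
`reference_matrix_effect()`, `reference_stability()`,
`reference_recovery()`) for worked examples and rule checks:

```r
mpa <- dplyr::filter(reference_mean_profiles(), analyte == "MPA")
find_cmax(mpa)   # 145.6 ng/mL at 1 h
find_cmax2(mpa)  # secondary peak 36.9 ng/mL at 12 h
auc_linear_trapezoid(mpa)  # 486.65 ng·h/mL
```

## Documentation

The methods vignette (`vignettes/salivapk-methods.Rmd`) describes the
response models and when each applies, the exact acceptance-rule
boundaries, the secondary-peak rule and BLQ handling, the agreement
statistics and their assumptions, what the synthetic-data generator does
and does not emulate, and the package's numerical conventions.
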