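---
title: "Models and methods behind salivapk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind salivapk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(salivapk)
library(dplyr)
```

`salivapk` models the complete data-analysis path of a targeted LC–MS/MS
assay for mycophenolic acid (MPA) and its glucuronide (MPAG) in saliva:
from peak-area run tables, through calibration and bioanalytical
validation, to non-compartmental pharmacokinetics (NCA) and cross-method
agreement. This vignette explains the models, the acceptance rules, the
synthetic-data generator, and the design choices that were genuinely open.

## 1. Quantification model

The instrument response of an injection is the analyte peak area divided
by the internal-standard (IS, deuterated MPA) peak area for MPA, and the
raw analyte peak area for MPAG — a deuterated glucuronide IS cannot be
used because it interferes at the parent's mass transition. Both
definitions are available through `compute_response()` and are
configurable per analyte in `analysis_config()`.

Calibration covers 2–500 ng/mL with eight standards
(2, 5, 10, 20, 50, 100, 200, 500 ng/mL). Two unweighted model forms are
implemented in `fit_calibration()`:

* **linear**, `y = a C + b`, ordinary least squares on the raw scale;
* **power**, `y = alpha C^beta`, least squares of `log y` on `log C`,
  reported as `alpha = exp(intercept)`, `beta = slope`.

The correlation coefficient `r` is reported on the scale the regression
was actually performed on (log–log for the power form). For the linear
form the intercept is tested against zero by a Student's t-test on
`n - 2` degrees of freedom; a non-significant intercept supports
proportionality through the origin. `back_calculate()` inverts the fitted
model; negative inverses are clipped to zero and flagged below the lower
limit of quantification (BLQ), values above the upper limit are flagged
unless a recorded dilution factor brings them back into range
(`apply_dilution()` multiplies *after* back-calculation).

**Which model to use when.** `fit_calibration()` defaults to the linear
form, which is exact and transparent when responses are noise-free or the
error is additive. `validate_run()`, in contrast, quantifies against the
power fit by default: measurement error in this kind of assay is close to
proportional (constant CV), and an unweighted straight-line fit over a
250-fold range then lets the top standards dominate the intercept — its
sampling error on the concentration scale is on the order of 10 ng/mL,
which makes back-calculation at a 2 ng/mL LLOQ meaningless. The
unweighted log–log fit absorbs proportional error homoscedastically and
back-calculates accurately across the whole range. No 1/x or 1/x²
weighting schemes are provided: the assay design this package models used
unweighted fits only.

## 2. Validation battery and acceptance rules

`validate_run()` executes every validation experiment from one run table,
using the record roles to assemble the designs. The verdict layer is
deliberately split from the aggregation layer: `verdict_*()` functions
are pure functions of summary metrics, so published summary tables can be
re-judged without replicate-level data, and every stored outcome can be
recomputed from its own metrics.

| Test | Metric | Rule |
|---|---|---|
| Accuracy/precision | mean/nominal ×100; CV (n−1 SD) | 85–115 % and ≤ 15 % (LLOQ: 80–120 %, ≤ 20 %), inclusive |
| Selectivity | blank response / reference | ≤ 20 % of LLOQ analyte response, ≤ 5 % of IS response, inclusive |
| Carry-over | post-ULOQ blank response / reference | **strictly below** the same 20 %/5 % fractions |
| Matrix effect | accuracy, CV per donor × level | 85–115 % and ≤ 15 % for every donor |
| Dilution integrity | relative error (= accuracy − 100), CV | \|RE\| ≤ 15 and CV ≤ 15 |
| Stability | mean percent of nominal per condition × level | 85–115 % |
| Swab recovery | mean percent of nominal, CV | 85–115 % and ≤ 15 % |

Two wording choices deserve a note. First, boundary inclusivity follows
the phrasing of each rule: "within ± 15 %" and "should not exceed" are
inclusive; carry-over's "below" is strict. Second, dilution integrity is
sometimes described by its accuracy (e.g. 109.1 %) and sometimes by the
equivalent relative error (9.1 %); both are computed and reported, and the
±15 bound is applied to the relative error, which reconciles the two
conventions exactly.

Within-run QC sets must come from a single run; between-run sets pool
replicates across at least two runs. The run layout of the between-run
experiment is not standardized, so it is configurable; the default spreads
five replicates per level over three additional runs (2/2/1).

## 3. Non-compartmental pharmacokinetics

Profiles are sampled at 0, 1, 2, 3, 4, 6, 9 and 12 h after dosing.
`compute_pk_parameters()` derives, from one BLQ-resolved profile:

* `auc_0_t` by the linear trapezoid rule (`auc_linear_trapezoid()`),
  with no extrapolation beyond the last sample and no log-linear variant —
  the reporting convention this package mirrors uses the plain trapezoid
  to 12 h only;
* `cmax`/`tmax`, ties broken by the earliest time;
* `cmax2`/`tmax2`, the enterohepatic-recirculation secondary peak.

The secondary-peak rule scans the points strictly after `tmax`: a point
qualifies when its concentration is at least 20 % above the immediately
preceding sample (`C_i >= 1.2 C_{i-1}`; any rise from zero qualifies).
Among qualifying points the largest concentration is reported — a
"secondary maximum", not the first rise. Restricting the scan to
`t > tmax` follows from the definition: a second maximum presupposes the
first. The threshold is configurable (`cmax2_threshold`), and detection
is applied to MPA by default; MPAG detection is available
(`cmax2_analytes` in `nca()`) but off, since glucuronide profiles decline
smoothly after their peak.

**BLQ handling.** Concentrations below the LLOQ (including an
undetectable pre-dose sample in a non-adherent patient) are substituted
by zero before AUC and summaries, configurable to LLOQ/2
(`blq_rule` in `analysis_config()`). A numeric substitution is required
for the AUC of such profiles to exist; zero is the conservative floor.

`summarize_cohort()` reports time-point means ± SD with CV%, and
parameter summaries as mean ± SD (CV%) except the time-to-peak parameters
`tmax` and `tmax2`, which are summarized as median and range. The
secondary peak is summarized over the subjects where it was detected,
with `n_with_cmax2` stated. Note that the trapezoid AUC of a cohort's
*mean* profile equals the mean of per-subject AUCs only when every
subject shares the grid and the same BLQ substitutions; summaries over
subjects and statistics of the mean profile are therefore distinct
quantities and are never mixed.

## 4. Method agreement

`compare_methods()` bundles three analyses of paired measurements
(`reference` = the LC–MS/MS method, `comparator` = the method compared
against it):

* **Bland–Altman** (`bland_altman()`): differences are
  `comparator − reference`, so a comparator reading lower gives a
  negative mean difference. Limits of agreement are mean ± 1.96 SD; the
  95 % CI of the mean difference uses the t distribution. Bias is judged
  by whether zero lies in that CI; agreement is "erratic" when more than
  5 % of points fall outside the limits.
* **Passing–Bablok** (`passing_bablok()`): the classical pairwise-slope
  procedure — all `C(n,2)` slopes; ties in both coordinates dropped;
  x-only ties contribute signed infinities at the ends of the sort;
  slopes exactly −1 discarded; the estimate is the median shifted by the
  count `K` of slopes below −1; CI bounds sit at rank offsets
  `w = z √(n(n−1)(2n+5)/18)`. The intercept is `median(y − slope·x)`,
  with its CI derived from the slope bounds. A slope CI excluding 1 flags
  proportional bias, an intercept CI excluding 0 constant bias.
* **Pearson correlation** with the exact t transform, gated by
  Shapiro–Wilk normality checks of both series (`normality_test()`).

The rank-based Passing–Bablok CI is distribution-free for exchangeable
errors. Under strongly heteroscedastic (proportional) noise its
finite-sample coverage drops slightly below nominal (we measure ≈ 89 %
instead of 95 % at n = 16); the package's coverage tests therefore use
additive iid noise, and users comparing methods across a wide
concentration range should read the CI as approximate. Which series plays
x and which y is a convention; this package documents its own (reference
on x) rather than guessing anyone else's.

## 5. The synthetic-data generator

The generator exists so the entire pipeline runs and is testable without
any deposited raw data. It emulates, rather than reproduces, the study
conditions.

**Double-peak profiles.** The base disposition is a Bateman curve
`C(t) = A(e^{−ke t} − e^{−ka t})`; enterohepatic recirculation is a
single delayed re-absorption pulse — the same Bateman term scaled by
`ehc_fraction` and shifted to `ehc_time` — rather than a gall-bladder
compartment ODE: two extra parameters reproduce the observed double peak
while every peak time stays analytically checkable. Defaults
(`A = 215` ng/mL, `ka = 2.5`/h, `ke = 0.3`/h, pulse at 8 h with fraction
0.4) put the typical subject's peak at the 1-h sample, a qualifying
≥ 20 % rise at 9 h, and concentrations inside the assay's calibrated
span. At steady state under twice-daily dosing the pre-dose sample is not
drug-free, so one previous dose (12 h earlier) contributes by default;
non-adherent subjects (a configurable fraction) lack it and present a
zero pre-dose concentration. MPAG is a delayed, scaled transform of the
parent curve with slower elimination (`metabolite_*` parameters), not a
mechanistic metabolite compartment — only its shape and range matter
downstream. Between-subject variability is lognormal on `A`, `ka`, `ke`
(CVs 0.6/0.25/0.25). Matching published cohort *means* numerically is
explicitly not a goal; the generator targets the qualitative shape
(parent peak at 1 h, metabolite peak at 2–3 h, secondary rise after the
pulse) and the observed ranges.

**Instrument runs.** `generate_validation_run()` emits every validation
experiment as one run table per the design in `validation_design()`:
8 standards (ascending), 5 carry-over blanks chained immediately after
the top standard, 7 selectivity blanks (one per donor), 4 × 5 within-run
and 4 × 5 between-run QCs, 7 × 2 × 3 matrix QCs, 5 dilution samples
(800 ng/mL injected at 400 after twofold dilution), 6 conditions × 2
levels × 3 stability QCs and 2 × 3 swab-recovery QCs — 149 records per
analyte. Expected responses come from true linear curves per analyte,
scaled by per-donor matrix factors, per-condition degradation factors and
per-analyte swab recoveries, perturbed by proportional (default CV 5 %)
and small additive error; blanks carry no IS, so their IS channel holds
only baseline noise. Carry-over contamination is modeled on the dedicated
post-ULOQ blanks (each inheriting a fraction of the previous injection's
analyte area); the other experiments are taken as carry-over-free, which
is what lets a single injected fault fail exactly its own test. Each
fault knob is scoped for the same reason: `qc_error_cv` touches only
QC-role records, matrix factors only their donor, degradation factors
only their condition.

**What passing tests do and do not show.** The generator draws clean
lognormal/normal noise, uses exactly linear true response curves, and has
no drift, no interfering co-medication signals, and no within-subject
variability between runs. Green tests demonstrate that the *rules and
estimators* are implemented correctly and discriminate injected
violations; they do not certify any real instrument or laboratory.

## 6. Numerical choices and degenerate inputs

* CV always uses the n−1 sample SD.
* Displayed report values round to one decimal; JSON output and all
  computations keep full precision.
* An all-zero profile is degenerate: `cmax = 0` at the earliest time,
  flagged, rather than an error — cohort code must survive a blank
  profile.
* Ties: earliest time wins for both `cmax` and among equal secondary
  candidates; exact-tie pairwise slopes keep their multiplicity.
* A zero preceding concentration qualifies any positive rise as a
  secondary-peak candidate (the 20 % ratio is undefined at zero; the
  limit of the rule as `C_{i-1} → 0` admits any rise).
* Back-calculated negatives clip to zero with a BLQ flag, preserving
  downstream NCA.
* `run_table()` collects *all* schema violations and reports them with
  row numbers in one error.

Problem sizes in the shipped tests were chosen to exercise the
asymptotics that matter while staying quick: Bland–Altman containment at
n = 10⁴, Passing–Bablok coverage over 200 replicates of n = 16, oracle
equivalence over 50 random panels of up to 25 pairs, and 20-replicate
batches for the noise-monotonicity property.

## 7. Known limitations

* No batch-to-batch recalibration or drift correction; one curve per
  analyte quantifies a whole campaign.
* No limit-of-detection estimation (only the LLOQ is defined), no
  incurred-sample reanalysis, no extraction-recovery-vs-neat experiment.
* NCA provides AUC to the last sample only — no λz extrapolation, no
  dose normalization, no compartmental fitting.
* The agreement module offers no Deming regression or repeated-measures
  Bland–Altman.
* The generator does not simulate chromatograms, co-medication chemistry,
  or covariate (weight/height) effects; instrument metadata is carried as
  inert key/value pairs.
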