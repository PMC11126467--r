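#' Analysis configuration
#'
#' Bundles the assay's fixed quantities: the calibrated range, the
#' calibration-standard levels, the four QC levels, the in vivo sampling
#' grid, the secondary-peak rise threshold, and how below-LLOQ values are
#' resolved before non-compartmental analysis. Units are ng/mL and hours
#' throughout the package.
#'
#' @param lloq Lower limit of quantification (ng/mL).
#' @param uloq Upper limit of quantification (ng/mL).
#' @param cal_levels Calibration-standard concentrations, ascending, from
#'   `lloq` to `uloq` (ng/mL).
#' @param qc_levels Named vector of QC concentrations with names
#'   `LLOQ`, `low`, `medium`, `high` (ng/mL).
#' @param is_nominal Internal-standard nominal concentration in matrix
#'   (ng/mL); carried as metadata.
#' @param sampling_times In vivo sampling grid (hours after dosing).
#' @param cmax2_threshold Minimum fractional rise over the preceding sample
#'   for a point to qualify as a secondary peak (default 0.20, i.e. 20%).
#' @param blq_rule How below-LLOQ concentrations enter AUC and summaries:
#'   `"zero"` (default) or `"half_lloq"`.
#' @param response_modes Named character vector mapping analyte to response
#'   definition: `"is_ratio"` (analyte area / IS area) or `"raw_area"`.
#' @param rng_seed Optional integer seed recorded for provenance.
#'
#' @return A list of class `analysis_config`.
#' @examples
#' cfg <- analysis_config()
#' cfg$cal_levels
#' @export
analysis_config <- function(lloq = 2,
                            uloq = 500,
                            cal_levels = c(2, 5, 10, 20, 50, 100, 200, 500),
                            qc_levels = c(LLOQ = 2, low = 5, medium = 200, high = 500),
                            is_nominal = 200,
                            sampling_times = c(0, 1, 2, 3, 4, 6, 9, 12),
                            cmax2_threshold = 0.20,
                            blq_rule = c("zero", "half_lloq"),
                            response_modes = c(MPA = "is_ratio", MPAG = "raw_area"),
                            rng_seed = NULL) {
  blq_rule <- match.arg(blq_rule)
  if (!is.numeric(lloq) || !is.numeric(uloq) || lloq <= 0 || lloq >= uloq) {
    abort("`lloq` must be positive and strictly below `uloq`.")
  }
  if (is.unsorted(cal_levels, strictly = TRUE)) {
    abort("`cal_levels` must be sorted strictly ascending.")
  }
  if (cal_levels[1] != lloq || cal_levels[length(cal_levels)] != uloq) {
    abort("`cal_levels` must start at `lloq` and end at `uloq`.")
  }
  required <- c("LLOQ", "low", "medium", "high")
  if (!all(required %in% names(qc_levels))) {
    abort("`qc_levels` must be named LLOQ, low, medium, high.")
  }
  if (cmax2_threshold <= 0 || cmax2_threshold >= 1) {
    abort("`cmax2_threshold` must lie strictly between 0 and 1.")
  }
  if (!all(response_modes %in% c("is_ratio", "raw_area"))) {
    abort("`response_modes` entries must be 'is_ratio' or 'raw_area'.")
  }
  structure(
    list(
      lloq = lloq, uloq = uloq,
      cal_levels = cal_levels,
      qc_levels = qc_levels[required],
      is_nominal = is_nominal,
      sampling_times = sampling_times,
      cmax2_threshold = cmax2_threshold,
      blq_rule = blq_rule,
      response_modes = response_modes,
      rng_seed = rng_seed
    ),
    class = "analysis_config"
  )
}

#' Acceptance criteria for the validation battery
#'
#' Bounds applied by the `assess_*` verdict functions. Defaults follow the
#' usual bioanalytical acceptance rules: accuracy within 85--115% of nominal
#' (80--120% at the LLOQ), CV at most 15% (20% at the LLOQ), blank
#' interference at most 20% of the LLOQ analyte response and 5% of the
#' internal-standard response, stability means within 85--115% of nominal,
#' and at most 5% of paired differences outside the Bland-Altman limits of
#' agreement. Accuracy/CV/stability bounds are inclusive; the carry-over
#' rule is strict ("below"), the selectivity rule inclusive ("not exceed").
#'
#' @param acc_low,acc_high Accuracy bounds (%) at non-LLOQ levels.
#' @param acc_low_lloq,acc_high_lloq Accuracy bounds (%) at the LLOQ.
#' @param cv_max Maximum CV (%) at non-LLOQ levels.
#' @param cv_max_lloq Maximum CV (%) at the LLOQ.
#' @param interference_max_analyte Blank analyte response as a fraction of
#'   the LLOQ analyte response.
#' @param interference_max_is Blank IS-channel response as a fraction of the
#'   internal-standard response.
#' @param stability_low,stability_high Stability mean-percent bounds (%).
#' @param outside_loa_max Tolerated fraction of points outside the
#'   Bland-Altman limits of agreement.
#'
#' @return A list of class `acceptance_criteria`.
#' @export
acceptance_criteria <- function(acc_low = 85, acc_high = 115,
                                acc_low_lloq = 80, acc_high_lloq = 120,
                                cv_max = 15, cv_max_lloq = 20,
                                interference_max_analyte = 0.20,
                                interference_max_is = 0.05,
                                stability_low = 85, stability_high = 115,
                                outside_loa_max = 0.05) {
  vals <- c(
    acc_low, acc_high, acc_low_lloq, acc_high_lloq, cv_max, cv_max_lloq,
    interference_max_analyte, interference_max_is,
    stability_low, stability_high, outside_loa_max
  )
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    abort("All acceptance bounds must be positive and finite.")
  }
  if (!(acc_low < 100 && 100 < acc_high) ||
      !(acc_low_lloq < 100 && 100 < acc_high_lloq) ||
      !(stability_low < 100 && 100 < stability_high)) {
    abort("Accuracy and stability bounds must bracket 100%.")
  }
  structure(
    list(
      acc_low = acc_low, acc_high = acc_high,
      acc_low_lloq = acc_low_lloq, acc_high_lloq = acc_high_lloq,
      cv_max = cv_max, cv_max_lloq = cv_max_lloq,
      interference_max_analyte = interference_max_analyte,
      interference_max_is = interference_max_is,
      stability_low = stability_low, stability_high = stability_high,
      outside_loa_max = outside_loa_max
    ),
    class = "acceptance_criteria"
  )
}
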