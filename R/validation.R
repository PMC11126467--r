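#' Accuracy and precision metrics
#'
#' `accuracy_percent()` is the mean measured concentration as a percent of
#' nominal; `cv_percent()` is the coefficient of variation using the n-1
#' sample standard deviation, as conventional in bioanalysis.
#'
#' @param measured Measured concentrations (ng/mL).
#' @param nominal Nominal concentration (ng/mL, > 0).
#' @return A percentage.
#' @examples
#' accuracy_percent(c(210, 214.8), 200) # 106.2
#' cv_percent(c(90, 100, 110))          # 10
#' @export
accuracy_percent <- function(measured, nominal) {
  if (length(measured) < 1) abort("`measured` must contain at least one value.")
  if (!is.numeric(nominal) || length(nominal) != 1 || nominal <= 0) {
    abort("`nominal` must be a single positive number.")
  }
  mean(measured) / nominal * 100
}

#' @rdname accuracy_percent
#' @export
cv_percent <- function(measured) {
  if (length(measured) < 2) abort("CV requires at least two replicates.")
  m <- mean(measured)
  if (m == 0) abort("CV undefined: mean of replicates is zero.")
  sd(measured) / m * 100
}

# verdict helpers -- pure functions of metrics and criteria, so printed
# summary values can be re-judged without the underlying replicates
qc_bounds <- function(is_lloq, criteria) {
  list(
    lo = ifelse(is_lloq, criteria$acc_low_lloq, criteria$acc_low),
    hi = ifelse(is_lloq, criteria$acc_high_lloq, criteria$acc_high),
    cv = ifelse(is_lloq, criteria$cv_max_lloq, criteria$cv_max)
  )
}

#' Verdicts from precomputed metrics
#'
#' Pure acceptance rules: each returns TRUE/FALSE from summary metrics
#' alone, so that published summary tables can be re-judged without the
#' underlying replicate measurements. Accuracy/CV/stability bounds are
#' inclusive; the carry-over bound is strict.
#'
#' @param accuracy Accuracy (% of nominal).
#' @param cv Coefficient of variation (%).
#' @param is_lloq Is this the LLOQ level (wider bounds apply)?
#' @param mean_percent Stability mean as a percent of nominal.
#' @param recovery Recovery (% of nominal).
#' @param analyte_fraction Blank analyte response / LLOQ analyte response.
#' @param is_fraction Blank IS-channel response / IS response.
#' @param criteria An [acceptance_criteria()].
#' @return Logical, vectorized over metrics.
#' @export
verdict_accuracy_cv <- function(accuracy, cv, is_lloq = FALSE,
                                criteria = acceptance_criteria()) {
  b <- qc_bounds(is_lloq, criteria)
  accuracy >= b$lo & accuracy <= b$hi & cv <= b$cv
}

#' @rdname verdict_accuracy_cv
#' @export
verdict_stability <- function(mean_percent, criteria = acceptance_criteria()) {
  mean_percent >= criteria$stability_low & mean_percent <= criteria$stability_high
}

#' @rdname verdict_accuracy_cv
#' @export
verdict_recovery <- function(recovery, cv, criteria = acceptance_criteria()) {
  recovery >= criteria$acc_low & recovery <= criteria$acc_high &
    cv <= criteria$cv_max
}

#' @rdname verdict_accuracy_cv
#' @export
verdict_selectivity <- function(analyte_fraction, is_fraction,
                                criteria = acceptance_criteria()) {
  analyte_fraction <= criteria$interference_max_analyte &
    is_fraction <= criteria$interference_max_is
}

#' @rdname verdict_accuracy_cv
#' @export
verdict_carryover <- function(analyte_fraction, is_fraction,
                              criteria = acceptance_criteria()) {
  analyte_fraction < criteria$interference_max_analyte &
    is_fraction < criteria$interference_max_is
}

outcome_row <- function(test, pass, analyte = NA_character_,
                        level = NA_character_, scope = NA_character_,
                        matrix_id = NA_character_, condition = NA_character_,
                        accuracy = NA_real_, cv = NA_real_,
                        mean_percent = NA_real_, recovery = NA_real_,
                        relative_error = NA_real_,
                        max_analyte_fraction = NA_real_,
                        max_is_fraction = NA_real_, n = NA_integer_,
                        detail = NA_character_) {
  tibble(
    test = test, analyte = analyte, level = level, scope = scope,
    matrix_id = matrix_id, condition = condition, accuracy = accuracy,
    cv = cv, mean_percent = mean_percent, recovery = recovery,
    relative_error = relative_error,
    max_analyte_fraction = max_analyte_fraction,
    max_is_fraction = max_is_fraction, n = n, pass = pass, detail = detail
  )
}

#' Within-run and between-run accuracy and precision
#'
#' Judges QC replicate sets at the four levels (LLOQ, low, medium, high).
#' A within-run set must come from a single run; a between-run set must
#' pool at least two distinct runs. Pass requires accuracy within 85--115%
#' of nominal and CV <= 15% (LLOQ: 80--120% and <= 20%).
#'
#' @param qc A data frame with one row per replicate: columns `analyte`,
#'   `level` (one of `LLOQ`, `low`, `medium`, `high`), `nominal`,
#'   `measured`, `run_id`, `scope` (`within_run`/`between_run`).
#' @param criteria An [acceptance_criteria()].
#' @return A tibble of test outcomes (one row per analyte x scope x
#'   level) with metrics and a `pass` verdict.
#' @export
assess_accuracy_precision <- function(qc, criteria = acceptance_criteria()) {
  qc <- as_tibble(qc)
  levels_needed <- c("LLOQ", "low", "medium", "high")
  design <- distinct(qc, .data$analyte, .data$scope, .data$level)
  for (an in unique(qc$analyte)) {
    for (sc in unique(qc$scope[qc$analyte == an])) {
      have <- design$level[design$analyte == an & design$scope == sc]
      if (!all(levels_needed %in% have)) {
        abort(paste0("Incomplete design: analyte ", an, " scope ", sc,
                     " is missing level(s) ",
                     paste(setdiff(levels_needed, have), collapse = ", "), "."))
      }
    }
  }
  qc %>%
    group_by(.data$analyte, .data$scope, .data$level, .data$nominal) %>%
    summarise(
      n_runs = dplyr::n_distinct(.data$run_id),
      n = dplyr::n(),
      accuracy = accuracy_percent(.data$measured, .data$nominal[1]),
      cv = cv_percent(.data$measured),
      .groups = "drop"
    ) %>%
    (function(df) {
      bad_within <- df$scope == "within_run" & df$n_runs > 1
      bad_between <- df$scope == "between_run" & df$n_runs < 2
      if (any(bad_within)) abort("within_run sets must come from a single run.")
      if (any(bad_between)) abort("between_run sets need >= 2 distinct runs.")
      df
    }) %>%
    mutate(
      pass = verdict_accuracy_cv(.data$accuracy, .data$cv,
                                 .data$level == "LLOQ", criteria)
    ) %>%
    (function(df) {
      bind_rows(purrr::pmap(df, function(analyte, scope, level, nominal,
                                         n_runs, n, accuracy, cv, pass) {
        outcome_row("accuracy_precision", pass, analyte = analyte,
                    level = level, scope = scope, accuracy = accuracy,
                    cv = cv, n = as.integer(n))
      }))
    })
}

#' Selectivity against blank-matrix interference
#'
#' For each blank-saliva donor, interfering signal at the analyte's
#' retention time must not exceed 20% of the analyte response at the LLOQ,
#' and signal in the IS channel must not exceed 5% of the IS response
#' (both inclusive).
#'
#' @param blanks A data frame with columns `analyte`, `matrix_id`,
#'   `analyte_response`, `is_response` (one row per blank specimen).
#' @param lloq_response Named-by-analyte (or single) reference analyte
#'   response at the LLOQ, > 0.
#' @param is_response Reference IS response, > 0.
#' @param criteria An [acceptance_criteria()].
#' @return A tibble of outcomes, one row per analyte x matrix.
#' @export
assess_selectivity <- function(blanks, lloq_response, is_response,
                               criteria = acceptance_criteria()) {
  blanks <- as_tibble(blanks)
  if (nrow(blanks) < 1) abort("At least one blank matrix is required.")
  if (any(lloq_response <= 0) || any(is_response <= 0)) {
    abort("Reference responses must be > 0.")
  }
  ref_lloq <- lloq_response
  ref_is <- is_response
  ref_for <- function(x, analyte) {
    if (!is.null(names(x))) unname(x[analyte]) else x[1]
  }
  blanks %>%
    group_by(.data$analyte, .data$matrix_id) %>%
    summarise(
      max_analyte_fraction =
        max(.data$analyte_response) / ref_for(.env$ref_lloq, .data$analyte[1]),
      max_is_fraction = max(.data$is_response) / ref_for(.env$ref_is,
                                                         .data$analyte[1]),
      n = dplyr::n(), .groups = "drop"
    ) %>%
    (function(df) {
      bind_rows(purrr::pmap(df, function(analyte, matrix_id,
                                         max_analyte_fraction,
                                         max_is_fraction, n) {
        outcome_row(
          "selectivity",
          verdict_selectivity(max_analyte_fraction, max_is_fraction, criteria),
          analyte = analyte, matrix_id = matrix_id,
          max_analyte_fraction = max_analyte_fraction,
          max_is_fraction = max_is_fraction, n = as.integer(n)
        )
      }))
    })
}

#' Carry-over in blanks injected after the upper calibration standard
#'
#' Every blank injected immediately after the ULOQ standard must show
#' analyte response strictly below 20% of the LLOQ analyte response and
#' IS-channel response strictly below 5% of the IS response.
#'
#' @param blanks A data frame with columns `analyte`, `analyte_response`,
#'   `is_response` (one row per post-ULOQ blank).
#' @inheritParams assess_selectivity
#' @return A tibble of outcomes, one row per analyte.
#' @export
assess_carryover <- function(blanks, lloq_response, is_response,
                             criteria = acceptance_criteria()) {
  blanks <- as_tibble(blanks)
  if (nrow(blanks) < 1) {
    abort("Incomplete design: no post-ULOQ blank injections found.")
  }
  if (any(lloq_response <= 0) || any(is_response <= 0)) {
    abort("Reference responses must be > 0.")
  }
  ref_lloq <- lloq_response
  ref_is <- is_response
  ref_for <- function(x, analyte) {
    if (!is.null(names(x))) unname(x[analyte]) else x[1]
  }
  blanks %>%
    group_by(.data$analyte) %>%
    summarise(
      max_analyte_fraction =
        max(.data$analyte_response) / ref_for(.env$ref_lloq, .data$analyte[1]),
      max_is_fraction = max(.data$is_response) / ref_for(.env$ref_is,
                                                         .data$analyte[1]),
      n = dplyr::n(), .groups = "drop"
    ) %>%
    (function(df) {
      bind_rows(purrr::pmap(df, function(analyte, max_analyte_fraction,
                                         max_is_fraction, n) {
        outcome_row(
          "carryover",
          verdict_carryover(max_analyte_fraction, max_is_fraction, criteria),
          analyte = analyte,
          max_analyte_fraction = max_analyte_fraction,
          max_is_fraction = max_is_fraction, n = as.integer(n)
        )
      }))
    })
}

#' Matrix effect across blank-saliva donors
#'
#' Replicate QCs at low and high level prepared in saliva from several
#' donors; every donor x level cell must show accuracy within 85--115% of
#' nominal and CV <= 15%.
#'
#' @param sets A data frame with one row per replicate: columns `analyte`,
#'   `matrix_id`, `level`, `nominal`, `measured`.
#' @param criteria An [acceptance_criteria()].
#' @return A tibble of outcomes, one row per analyte x matrix x level.
#' @export
assess_matrix_effect <- function(sets, criteria = acceptance_criteria()) {
  sets <- as_tibble(sets)
  n_mat <- dplyr::n_distinct(sets$matrix_id)
  if (n_mat < 2) abort("Incomplete design: at least 2 matrices are required.")
  counts <- sets %>%
    group_by(.data$analyte, .data$matrix_id, .data$level) %>%
    summarise(n = dplyr::n(), .groups = "drop")
  if (any(counts$n < 3)) {
    abort("Incomplete design: at least 3 replicates per matrix and level.")
  }
  sets %>%
    group_by(.data$analyte, .data$matrix_id, .data$level, .data$nominal) %>%
    summarise(
      n = dplyr::n(),
      accuracy = accuracy_percent(.data$measured, .data$nominal[1]),
      cv = cv_percent(.data$measured), .groups = "drop"
    ) %>%
    (function(df) {
      bind_rows(purrr::pmap(df, function(analyte, matrix_id, level, nominal,
                                         n, accuracy, cv) {
        outcome_row(
          "matrix_effect",
          verdict_accuracy_cv(accuracy, cv, FALSE, criteria),
          analyte = analyte, matrix_id = matrix_id, level = level,
          accuracy = accuracy, cv = cv, n = as.integer(n)
        )
      }))
    })
}

#' Dilution integrity
#'
#' Over-range samples (prepared at `prepared_conc`, diluted by `factor`
#' into the calibrated range) must recover the prepared concentration:
#' the mean relative error (accuracy - 100) must be within +/- 15% and the
#' CV at most 15%. Both the accuracy percent and the relative error are
#' reported.
#'
#' @param measured Dilution-corrected concentrations (back-calculation x
#'   dilution factor), n >= 2, possibly per analyte via `analyte`.
#' @param prepared_conc Prepared over-range concentration (ng/mL).
#' @param factor Dilution factor used.
#' @param analyte Analyte label for the outcome row.
#' @param criteria An [acceptance_criteria()].
#' @return A one-row outcome tibble.
#' @export
assess_dilution_integrity <- function(measured, prepared_conc = 800,
                                      factor = 2, analyte = NA_character_,
                                      criteria = acceptance_criteria()) {
  if (length(measured) < 2) abort("Dilution integrity needs >= 2 replicates.")
  if (factor < 1) abort("Dilution factor must be >= 1.")
  acc <- accuracy_percent(measured, prepared_conc)
  re <- acc - 100
  cv <- cv_percent(measured)
  pass <- abs(re) <= (criteria$acc_high - 100) & cv <= criteria$cv_max
  outcome_row("dilution_integrity", pass, analyte = analyte,
              accuracy = acc, relative_error = re, cv = cv,
              n = length(measured),
              detail = paste0("prepared ", prepared_conc, " ng/mL, diluted ",
                              factor, "-fold"))
}

#' Stability under storage and handling conditions
#'
#' Replicate QCs at low and high level, stored under each condition and
#' quantified against a fresh calibration curve; the mean concentration,
#' as a percent of nominal, must stay within 85--115% at both levels.
#'
#' @param sets A data frame with one row per replicate: columns `analyte`,
#'   `condition`, `level`, `nominal`, `measured`.
#' @param criteria An [acceptance_criteria()].
#' @return A tibble of outcomes, one row per analyte x condition x level.
#' @export
assess_stability <- function(sets, criteria = acceptance_criteria()) {
  sets <- as_tibble(sets)
  design <- sets %>%
    group_by(.data$analyte, .data$condition) %>%
    summarise(n_levels = dplyr::n_distinct(.data$level), .groups = "drop")
  if (any(design$n_levels < 2)) {
    abort("Incomplete design: each condition needs both QC levels.")
  }
  counts <- sets %>%
    group_by(.data$analyte, .data$condition, .data$level) %>%
    summarise(n = dplyr::n(), .groups = "drop")
  if (any(counts$n < 3)) {
    abort("Incomplete design: at least 3 replicates per condition and level.")
  }
  sets %>%
    group_by(.data$analyte, .data$condition, .data$level, .data$nominal) %>%
    summarise(
      n = dplyr::n(),
      mean_percent = accuracy_percent(.data$measured, .data$nominal[1]),
      .groups = "drop"
    ) %>%
    (function(df) {
      bind_rows(purrr::pmap(df, function(analyte, condition, level, nominal,
                                         n, mean_percent) {
        outcome_row(
          "stability", verdict_stability(mean_percent, criteria),
          analyte = analyte, condition = condition, level = level,
          mean_percent = mean_percent, n = as.integer(n)
        )
      }))
    })
}

#' Recovery from collection-device cotton swabs
#'
#' QCs spiked onto Salivette swabs and recovered through the normal
#' preparation; recovery (mean as a percent of nominal) must be within
#' 85--115% with CV <= 15% at both levels.
#'
#' @param sets A data frame with one row per replicate: columns `analyte`,
#'   `level`, `nominal`, `measured`.
#' @param criteria An [acceptance_criteria()].
#' @return A tibble of outcomes, one row per analyte x level.
#' @export
assess_recovery <- function(sets, criteria = acceptance_criteria()) {
  sets <- as_tibble(sets)
  counts <- sets %>%
    group_by(.data$analyte, .data$level) %>%
    summarise(n = dplyr::n(), .groups = "drop")
  if (any(counts$n < 2)) abort("Recovery needs >= 2 replicates per level.")
  sets %>%
    group_by(.data$analyte, .data$level, .data$nominal) %>%
    summarise(
      n = dplyr::n(),
      recovery = accuracy_percent(.data$measured, .data$nominal[1]),
      cv = cv_percent(.data$measured), .groups = "drop"
    ) %>%
    (function(df) {
      bind_rows(purrr::pmap(df, function(analyte, level, nominal, n,
                                         recovery, cv) {
        outcome_row(
          "recovery", verdict_recovery(recovery, cv, criteria),
          analyte = analyte, level = level, recovery = recovery, cv = cv,
          n = as.integer(n)
        )
      }))
    })
}

#' Compile validation outcomes into a report
#'
#' @param outcomes A tibble (or list of tibbles) of outcomes from the
#'   `assess_*` functions.
#' @param criteria The [acceptance_criteria()] the verdicts used.
#' @param config Optional [analysis_config()] snapshot.
#' @return An object of class `validation_report` with elements
#'   `outcomes`, `overall_pass`, `criteria`, `config`. `overall_pass` is
#'   TRUE iff every outcome passes.
#' @export
compile_report <- function(outcomes, criteria = acceptance_criteria(),
                           config = NULL) {
  if (is.data.frame(outcomes)) outcomes <- list(outcomes)
  outcomes <- bind_rows(outcomes)
  if (nrow(outcomes) == 0) abort("At least one outcome is required.")
  structure(
    list(
      outcomes = outcomes,
      overall_pass = all(outcomes$pass),
      criteria = criteria,
      config = config
    ),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  writeLines(report_text(x))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.validation_report <- function(x, ...) x$outcomes

#' @exportS3Method generics::glance
glance.validation_report <- function(x, ...) {
  x$outcomes %>%
    group_by(.data$test) %>%
    summarise(n_outcomes = dplyr::n(), n_fail = sum(!.data$pass),
              pass = all(.data$pass), .groups = "drop")
}
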