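#' Build and validate a run table
#'
#' A run table is one tibble row per instrument injection: sample identity,
#' its role in the run, the analyte, the nominal concentration where one
#' exists, the analyte and internal-standard peak areas, and run/matrix/
#' condition labels. Free-form instrument metadata (column settings, MRM
#' transitions, ...) rides along as an attribute and is never interpreted.
#'
#' Schema rules enforced here (violations are collected and reported
#' together):
#' * `role` and `analyte` must come from their closed vocabularies;
#' * peak areas must be non-negative;
#' * `nominal_conc` must be present for every role except blank/unknown and
#'   absent for blanks;
#' * `dilution_factor` must be >= 1, and equal to 1 unless the role is
#'   `dilution_qc` or `unknown`;
#' * `injection_order` must be unique within each `run_id`.
#'
#' @param records A data frame with columns `sample_id`, `role`, `analyte`,
#'   `analyte_area`, `run_id`, `injection_order`, and optionally
#'   `nominal_conc`, `is_area`, `matrix_id`, `condition`,
#'   `dilution_factor`.
#' @param metadata Named list of free-form key/value metadata.
#'
#' @return A tibble of class `run_table`, ordered by (`run_id`,
#'   `injection_order`), with a `metadata` attribute.
#' @export
run_table <- function(records, metadata = list()) {
  records <- as_tibble(records)
  required <- c("sample_id", "role", "analyte", "analyte_area", "run_id",
                "injection_order")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0) {
    abort(paste0("Run table is missing required column(s): ",
                 paste(missing_cols, collapse = ", "), "."))
  }
  if (nrow(records) == 0) {
    abort("A run table must contain at least one record.")
  }
  optional_defaults <- list(
    nominal_conc = NA_real_, is_area = NA_real_, matrix_id = NA_character_,
    condition = NA_character_, dilution_factor = 1
  )
  for (col in names(optional_defaults)) {
    if (!col %in% names(records)) records[[col]] <- optional_defaults[[col]]
  }
  records <- records %>%
    mutate(
      sample_id = as.character(.data$sample_id),
      role = as.character(.data$role),
      analyte = as.character(.data$analyte),
      nominal_conc = as.numeric(.data$nominal_conc),
      analyte_area = as.numeric(.data$analyte_area),
      is_area = as.numeric(.data$is_area),
      run_id = as.character(.data$run_id),
      matrix_id = as.character(.data$matrix_id),
      condition = as.character(.data$condition),
      dilution_factor = dplyr::coalesce(as.numeric(.data$dilution_factor), 1),
      injection_order = as.integer(.data$injection_order)
    ) %>%
    select(
      "sample_id", "role", "analyte", "nominal_conc", "analyte_area",
      "is_area", "run_id", "matrix_id", "condition", "dilution_factor",
      "injection_order"
    )

  problems <- character()
  bad <- function(idx, what) {
    if (length(idx) > 0) {
      problems <<- c(problems, paste0(what, " (row ",
                                      paste(idx, collapse = ", "), ")"))
    }
  }
  bad(which(!records$role %in% .roles), "unknown role")
  bad(which(!records$analyte %in% .analytes), "unknown analyte")
  bad(which(is.na(records$analyte_area) | records$analyte_area < 0),
      "negative or missing analyte_area")
  bad(which(!is.na(records$is_area) & records$is_area < 0),
      "negative is_area")
  needs_nominal <- !records$role %in% c("blank", "unknown")
  bad(which(needs_nominal & !is.finite(records$nominal_conc)),
      "nominal_conc required for this role")
  bad(which(records$role == "blank" & is.finite(records$nominal_conc)),
      "blank records must not carry nominal_conc")
  bad(which(is.na(records$dilution_factor) | records$dilution_factor < 1),
      "dilution_factor must be >= 1")
  bad(which(records$dilution_factor != 1 &
              !records$role %in% c("dilution_qc", "unknown")),
      "dilution_factor must be 1 for this role")
  dup <- records %>%
    group_by(.data$run_id, .data$injection_order) %>%
    mutate(.dup = dplyr::n() > 1) %>%
    pull(".dup")
  bad(which(dup), "duplicate injection_order within run_id")
  if (length(problems) > 0) {
    abort(paste0("Invalid run table:\n  - ",
                 paste(problems, collapse = "\n  - ")))
  }

  out <- arrange(records, .data$run_id, .data$injection_order)
  attr(out, "metadata") <- metadata
  class(out) <- c("run_table", class(out))
  out
}

#' Read or write a run table as delimited text
#'
#' The on-disk form is a comma-separated UTF-8 file with a mandatory header;
#' metadata is serialized as `#key: value` comment lines before the header.
#' Text columns round-trip bit-identically; numerics round-trip to full
#' printed precision.
#'
#' @param path File path.
#' @param config An [analysis_config()] (recorded on the returned table).
#' @param table A `run_table`.
#' @return `read_run_table()` a `run_table`; `write_run_table()` the path,
#'   invisibly.
#' @examples
#' tmp <- tempfile(fileext = ".csv")
#' rt <- run_table(tibble::tibble(
#'   sample_id = "CAL-1", role = "cal_standard", analyte = "MPA",
#'   nominal_conc = 2, analyte_area = 2100, is_area = 201000,
#'   run_id = "run-1", injection_order = 1
#' ))
#' write_run_table(rt, tmp)
#' read_run_table(tmp)
#' @export
read_run_table <- function(path, config = analysis_config()) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  meta <- read_comment_metadata(path)
  records <- readr::read_csv(
    path, comment = "#", show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(.default = readr::col_guess())
  )
  out <- run_table(records, metadata = meta)
  attr(out, "config") <- config
  out
}

#' @rdname read_run_table
#' @export
write_run_table <- function(table, path) {
  if (!inherits(table, "run_table")) table <- run_table(table)
  if (nrow(table) == 0) abort("Refusing to write an empty run table.")
  write_with_metadata(as_tibble(table), attr(table, "metadata"), path)
  invisible(path)
}

#' Read or write a concentration-time profile table
#'
#' One row per (subject, analyte, time point): `subject_id`, `analyte`,
#' `time_h`, `conc` (ng/mL) and `blq_flag` marking values below the LLOQ.
#' The flag is recomputed from `config$lloq` on read so that it always
#' agrees with the configured assay range.
#'
#' @inheritParams read_run_table
#' @param profiles A data frame with the columns above (`blq_flag`
#'   optional).
#' @return `read_profile_table()` a tibble of class `profile_table`;
#'   `write_profile_table()` the path, invisibly.
#' @export
read_profile_table <- function(path, config = analysis_config()) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  meta <- read_comment_metadata(path)
  profiles <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                              progress = FALSE)
  out <- profile_table(profiles, config = config)
  attr(out, "metadata") <- meta
  out
}

#' @rdname read_profile_table
#' @export
profile_table <- function(profiles, config = analysis_config()) {
  profiles <- as_tibble(profiles)
  required <- c("subject_id", "analyte", "time_h", "conc")
  missing_cols <- setdiff(required, names(profiles))
  if (length(missing_cols) > 0) {
    abort(paste0("Profile table is missing required column(s): ",
                 paste(missing_cols, collapse = ", "), "."))
  }
  profiles <- profiles %>%
    mutate(
      subject_id = as.character(.data$subject_id),
      analyte = as.character(.data$analyte),
      time_h = as.numeric(.data$time_h),
      conc = as.numeric(.data$conc),
      blq_flag = .data$conc < config$lloq
    ) %>%
    select("subject_id", "analyte", "time_h", "conc", "blq_flag")
  if (any(!profiles$analyte %in% .analytes)) abort("Unknown analyte in profile table.")
  if (any(profiles$time_h < 0) || any(profiles$conc < 0)) {
    abort("Profile times and concentrations must be non-negative.")
  }
  if (anyDuplicated(profiles[c("subject_id", "analyte", "time_h")]) > 0) {
    abort("Duplicate (subject_id, analyte, time_h) in profile table.")
  }
  class(profiles) <- c("profile_table", class(profiles))
  profiles
}

#' @rdname read_profile_table
#' @export
write_profile_table <- function(profiles, path) {
  write_with_metadata(as_tibble(profiles), attr(profiles, "metadata"), path)
  invisible(path)
}

read_comment_metadata <- function(path) {
  lines <- readLines(path, n = 200L, warn = FALSE)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    m <- regmatches(ln, regexec("^#\\s*([^:]+):\\s*(.*)$", ln))[[1]]
    if (length(m) == 3) meta[[trimws(m[2])]] <- trimws(m[3])
  }
  meta
}

write_with_metadata <- function(df, metadata, path) {
  lines <- character()
  if (length(metadata) > 0) {
    lines <- paste0("#", names(metadata), ": ",
                    vapply(metadata, as.character, character(1)))
  }
  body <- readr::format_csv(df)
  out <- tryCatch(
    writeLines(c(lines, sub("\n$", "", body)), path, useBytes = TRUE),
    error = function(e) abort(paste0("Cannot write to ", path))
  )
  invisible(path)
}

#' Write a report to JSON or plain text
#'
#' The JSON form carries every computed metric and verdict at full
#' precision and is a fixed point under parse/serialize. The text form is
#' for reading: accuracy, CV and recovery values are rounded to one
#' decimal, and report sections with no outcomes render as "not assessed".
#'
#' @param report A [validation_report][compile_report()], a
#'   [cohort_summary][summarize_cohort()], or an
#'   [agreement_result][compare_methods()].
#' @param path Output file path.
#' @param format `"json"` or `"text"`.
#' @return The path, invisibly.
#' @export
write_report <- function(report, path, format = c("json", "text")) {
  if (length(format) != 1 || !format %in% c("json", "text")) {
    if (identical(format, c("json", "text"))) {
      format <- "json"
    } else {
      abort("`format` must be \"json\" or \"text\".")
    }
  }
  if (format == "json") {
    jsonlite::write_json(report_payload(report), path,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
  } else {
    writeLines(report_text(report), path)
  }
  invisible(path)
}

report_payload <- function(report) {
  UseMethod("report_payload")
}

#' @export
report_payload.validation_report <- function(report) {
  list(
    report_type = "validation",
    overall_pass = report$overall_pass,
    outcomes = report$outcomes,
    criteria = unclass(report$criteria)
  )
}

#' @export
report_payload.cohort_summary <- function(report) {
  list(
    report_type = "nca_cohort",
    n = report$n,
    n_with_cmax2 = report$n_with_cmax2,
    timepoints = report$timepoints,
    parameters = report$parameters
  )
}

#' @export
report_payload.agreement_result <- function(report) {
  list(
    report_type = "method_agreement",
    n = report$n,
    bland_altman = unclass(tidy(report$bland_altman))[],
    passing_bablok = unclass(tidy(report$passing_bablok))[],
    pearson = unclass(tidy(report$pearson))[],
    normality = report$normality
  )
}

#' @export
report_payload.default <- function(report) {
  abort("Unknown report type; expected a validation report, cohort summary, or agreement result.")
}

fmt1 <- function(x) formatC(x, format = "f", digits = 1)

report_text <- function(report) {
  UseMethod("report_text")
}

#' @export
report_text.validation_report <- function(report) {
  tests <- c(
    "accuracy_precision", "selectivity", "carryover", "matrix_effect",
    "dilution_integrity", "stability", "recovery"
  )
  out <- c("Validation report",
           paste0("Overall: ", if (report$overall_pass) "PASS" else "FAIL"), "")
  for (tst in tests) {
    rows <- filter(report$outcomes, .data$test == tst)
    out <- c(out, paste0("== ", tst, " =="))
    if (nrow(rows) == 0) {
      out <- c(out, "  not assessed", "")
      next
    }
    for (i in seq_len(nrow(rows))) {
      r <- rows[i, ]
      labels <- c(r$analyte, r$level, r$scope, r$matrix_id, r$condition)
      labels <- labels[!is.na(labels)]
      metrics <- c(
        if (is.finite(r$accuracy)) paste0("accuracy ", fmt1(r$accuracy), "%"),
        if (is.finite(r$cv)) paste0("CV ", fmt1(r$cv), "%"),
        if (is.finite(r$mean_percent)) paste0("mean ", fmt1(r$mean_percent), "%"),
        if (is.finite(r$recovery)) paste0("recovery ", fmt1(r$recovery), "%"),
        if (is.finite(r$relative_error)) paste0("RE ", fmt1(r$relative_error), "%"),
        if (is.finite(r$max_analyte_fraction))
          paste0("analyte fraction ", fmt1(100 * r$max_analyte_fraction), "%"),
        if (is.finite(r$max_is_fraction))
          paste0("IS fraction ", fmt1(100 * r$max_is_fraction), "%")
      )
      out <- c(out, paste0(
        "  ", paste(labels, collapse = " / "), ": ",
        paste(metrics, collapse = ", "),
        " -> ", if (r$pass) "pass" else "FAIL"
      ))
    }
    out <- c(out, "")
  }
  out
}

#' @export
report_text.cohort_summary <- function(report) {
  out <- c("Non-compartmental cohort summary",
           paste0("Subjects: ", report$n,
                  " (secondary peak in ", report$n_with_cmax2, ")"), "",
           "Time-point means (ng/mL):")
  tp <- report$timepoints
  for (i in seq_len(nrow(tp))) {
    out <- c(out, paste0(
      "  ", tp$analyte[i], " t=", tp$time_h[i], " h: ",
      fmt1(tp$mean[i]), " +/- ", fmt1(tp$sd[i]),
      " (CV ", fmt1(tp$cv[i]), "%)"
    ))
  }
  out <- c(out, "", "Parameters:")
  pars <- report$parameters
  for (i in seq_len(nrow(pars))) {
    p <- pars[i, ]
    body <- if (p$summary_type == "median_range") {
      paste0("median ", fmt1(p$median), " (range ", fmt1(p$range_low),
             "-", fmt1(p$range_high), ")")
    } else {
      paste0(fmt1(p$mean), " +/- ", fmt1(p$sd), " (CV ", fmt1(p$cv), "%)")
    }
    out <- c(out, paste0("  ", p$analyte, " ", p$parameter, ": ", body,
                         " [n=", p$n, "]"))
  }
  out
}

#' @export
report_text.agreement_result <- function(report) {
  ba <- report$bland_altman
  pb <- report$passing_bablok
  pr <- report$pearson
  c(
    "Method-agreement report",
    paste0("n pairs: ", report$n),
    "",
    "Bland-Altman (comparator - reference):",
    paste0("  mean difference ", fmt1(ba$mean_diff),
           " (95% CI ", fmt1(ba$ci_mean_diff[1]), " to ",
           fmt1(ba$ci_mean_diff[2]), ")"),
    paste0("  limits of agreement ", fmt1(ba$loa_low), " to ",
           fmt1(ba$loa_high)),
    paste0("  points outside limits: ", ba$n_outside, " (",
           fmt1(100 * ba$prop_outside), "%)",
           if (ba$erratic_flag) " -> erratic variability" else ""),
    "",
    "Passing-Bablok:",
    paste0("  slope ", formatC(pb$slope, format = "f", digits = 4),
           " (95% CI ", formatC(pb$slope_ci[1], format = "f", digits = 4),
           " to ", formatC(pb$slope_ci[2], format = "f", digits = 4), ")"),
    paste0("  intercept ", formatC(pb$intercept, format = "f", digits = 4),
           " (95% CI ", formatC(pb$intercept_ci[1], format = "f", digits = 4),
           " to ", formatC(pb$intercept_ci[2], format = "f", digits = 4), ")"),
    paste0("  proportional bias: ", if (pb$proportional_bias) "yes" else "no",
           "; constant bias: ", if (pb$constant_bias) "yes" else "no"),
    "",
    paste0("Pearson r = ", formatC(pr$r, format = "f", digits = 4),
           ", p = ", format.pval(pr$p_value, digits = 4))
  )
}
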