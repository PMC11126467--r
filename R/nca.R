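#' Area under the concentration-time curve by the linear trapezoid rule
#'
#' Sums `(t[i+1] - t[i]) * (C[i] + C[i+1]) / 2` over adjacent sampling
#' points up to `t_end`. If `t_end` falls between grid points the last
#' segment is evaluated at the linearly interpolated concentration; no
#' extrapolation beyond the last observed time is performed.
#'
#' @param profile A data frame with columns `time_h` (strictly increasing)
#'   and `conc` (ng/mL), one subject-analyte profile.
#' @param t_end Upper integration limit (h); defaults to the last time.
#' @return AUC in ng.h/mL.
#' @examples
#' prof <- tibble::tibble(time_h = c(0, 1, 2, 3, 4, 6, 9, 12), conc = 10)
#' auc_linear_trapezoid(prof) # 120
#' @export
auc_linear_trapezoid <- function(profile, t_end = NULL) {
  profile <- as_tibble(profile)
  tt <- profile$time_h
  cc <- profile$conc
  if (length(tt) < 2) abort("AUC needs at least two sampling points.")
  if (is.unsorted(tt, strictly = TRUE)) {
    abort("Profile times must be strictly increasing.")
  }
  t_end <- t_end %||% max(tt)
  if (t_end > max(tt)) {
    abort("Extrapolation error: t_end lies beyond the last sampling time.")
  }
  if (t_end < min(tt)) abort("`t_end` precedes the first sampling time.")
  keep <- tt <= t_end
  tt2 <- tt[keep]
  cc2 <- cc[keep]
  if (t_end > max(tt2)) {
    c_end <- stats::approx(tt, cc, xout = t_end)$y
    tt2 <- c(tt2, t_end)
    cc2 <- c(cc2, c_end)
  }
  sum(diff(tt2) * (head(cc2, -1) + tail(cc2, -1)) / 2)
}

#' Maximum concentration and its time
#'
#' Returns the maximum observed concentration and the earliest time at
#' which it occurs (ties broken by earliest time). An all-zero profile is
#' degenerate: `cmax = 0` at the earliest time, flagged.
#'
#' @param profile A data frame with columns `time_h` and `conc`.
#' @return A one-row tibble: `cmax` (ng/mL), `tmax` (h), `degenerate`.
#' @export
find_cmax <- function(profile) {
  profile <- as_tibble(profile)
  if (nrow(profile) < 2) abort("A profile needs at least two points.")
  cc <- profile$conc
  if (all(cc == 0)) {
    return(tibble(cmax = 0, tmax = min(profile$time_h), degenerate = TRUE))
  }
  i <- which.max(cc) # which.max returns the first maximum: earliest time
  tibble(cmax = cc[i], tmax = profile$time_h[i], degenerate = FALSE)
}

#' Secondary (enterohepatic-recirculation) peak
#'
#' Scans the points strictly after `tmax`. A point qualifies when its
#' concentration has risen by at least `threshold` (default 20%) over the
#' immediately preceding sample, i.e. `C[i] >= (1 + threshold) * C[i-1]`;
#' any rise from a zero preceding concentration qualifies. Among
#' qualifying points the one with the largest concentration is returned
#' (ties broken by earliest time). When no point qualifies the secondary
#' peak is absent.
#'
#' @param profile A data frame with columns `time_h` and `conc`.
#' @param tmax Time of the primary maximum (h); computed from the profile
#'   when not supplied.
#' @param threshold Minimum fractional rise (default 0.20).
#' @return A one-row tibble: `cmax2`, `tmax2` (both `NA` when absent) and
#'   `detected`.
#' @examples
#' prof <- dplyr::filter(reference_mean_profiles(), analyte == "MPA")
#' find_cmax2(prof) # 36.9 ng/mL at 12 h
#' @export
find_cmax2 <- function(profile, tmax = NULL, threshold = 0.20) {
  profile <- as_tibble(profile)
  tmax <- tmax %||% find_cmax(profile)$tmax
  tt <- profile$time_h
  cc <- profile$conc
  idx <- which(tt > tmax)
  qualifying <- idx[vapply(idx, function(i) {
    prev <- cc[i - 1]
    if (prev == 0) cc[i] > 0 else cc[i] >= (1 + threshold) * prev
  }, logical(1))]
  if (length(qualifying) == 0) {
    return(tibble(cmax2 = NA_real_, tmax2 = NA_real_, detected = FALSE))
  }
  best <- qualifying[which.max(cc[qualifying])]
  tibble(cmax2 = cc[best], tmax2 = tt[best], detected = TRUE)
}

resolve_blq <- function(profile, config) {
  sub <- switch(config$blq_rule, zero = 0, half_lloq = config$lloq / 2)
  profile %>%
    mutate(conc = ifelse(.data$conc < config$lloq, sub, .data$conc))
}

#' Non-compartmental parameters of one profile
#'
#' Resolves below-LLOQ concentrations per the configured rule (0 by
#' default, optionally LLOQ/2), then computes AUC(0--t_end) by the linear
#' trapezoid rule, the primary maximum, and the secondary peak by the
#' >= 20%-rise rule. All parameters come from the same BLQ-resolved
#' profile.
#'
#' @param profile One subject-analyte profile: columns `time_h`, `conc`,
#'   and optionally `blq_flag`.
#' @param config An [analysis_config()].
#' @param t_end Upper AUC limit (h); defaults to the last grid time.
#' @param detect_cmax2 Whether to run secondary-peak detection (on for
#'   MPA-style parent profiles; MPAG detection is available but off in
#'   [nca()] by default).
#' @return A one-row tibble: `auc_0_t`, `cmax`, `tmax`, `cmax2`, `tmax2`,
#'   `cmax2_detected`, `degenerate`.
#' @export
compute_pk_parameters <- function(profile, config = analysis_config(),
                                  t_end = NULL, detect_cmax2 = TRUE) {
  profile <- resolve_blq(as_tibble(profile), config)
  profile <- arrange(profile, .data$time_h)
  pk <- find_cmax(profile)
  second <- if (detect_cmax2) {
    find_cmax2(profile, tmax = pk$tmax, threshold = config$cmax2_threshold)
  } else {
    tibble(cmax2 = NA_real_, tmax2 = NA_real_, detected = FALSE)
  }
  tibble(
    auc_0_t = auc_linear_trapezoid(profile, t_end = t_end),
    cmax = pk$cmax,
    tmax = pk$tmax,
    cmax2 = second$cmax2,
    tmax2 = second$tmax2,
    cmax2_detected = second$detected,
    degenerate = pk$degenerate
  )
}

#' Non-compartmental analysis of a profile table
#'
#' Runs [compute_pk_parameters()] for every subject x analyte profile.
#' Secondary-peak detection is applied to the analytes in `cmax2_analytes`
#' (the recirculating parent by default; the glucuronide can be opted in).
#'
#' @param profiles A [profile_table()]-shaped data frame (`subject_id`,
#'   `analyte`, `time_h`, `conc`).
#' @param config An [analysis_config()].
#' @param cmax2_analytes Analytes for which the secondary-peak rule runs.
#' @return A tibble with one row per subject x analyte.
#' @export
nca <- function(profiles, config = analysis_config(),
                cmax2_analytes = "MPA") {
  as_tibble(profiles) %>%
    group_by(.data$subject_id, .data$analyte) %>%
    dplyr::group_modify(function(df, key) {
      compute_pk_parameters(df, config,
                            detect_cmax2 = key$analyte %in% cmax2_analytes)
    }) %>%
    ungroup()
}

#' Cohort summary in the study's reporting conventions
#'
#' Per-time-point mean, SD and CV% of the concentrations, and per-parameter
#' summaries: mean +/- SD with CV% for AUC and concentrations, median and
#' range for the time-to-peak parameters (`tmax`, `tmax2`). The secondary
#' peak is summarized over the subjects in which it was detected, with
#' `n_with_cmax2` reported.
#'
#' @param profiles A profile table covering all subjects on a common
#'   sampling grid.
#' @param params Per-subject parameters from [nca()].
#' @return An object of class `cohort_summary`: list with `timepoints`,
#'   `parameters`, `n`, `n_with_cmax2`.
#' @export
summarize_cohort <- function(profiles, params) {
  profiles <- as_tibble(profiles)
  params <- as_tibble(params)
  if (dplyr::n_distinct(profiles$subject_id) < 2) {
    abort("A cohort summary needs at least two subjects.")
  }
  grids <- profiles %>%
    group_by(.data$subject_id, .data$analyte) %>%
    summarise(grid = paste(sort(.data$time_h), collapse = ","),
              .groups = "drop")
  if (dplyr::n_distinct(grids$grid) > 1) {
    abort("Alignment error: subjects are not on a common sampling grid.")
  }
  timepoints <- profiles %>%
    group_by(.data$analyte, .data$time_h) %>%
    summarise(
      mean = mean(.data$conc),
      sd = sd(.data$conc),
      cv = sd(.data$conc) / mean(.data$conc) * 100,
      n = dplyr::n(), .groups = "drop"
    )

  mean_sd_row <- function(df, parameter, values) {
    tibble(
      analyte = df$analyte[1], parameter = parameter,
      summary_type = "mean_sd",
      mean = mean(values), sd = sd(values),
      cv = sd(values) / mean(values) * 100,
      median = NA_real_, range_low = NA_real_, range_high = NA_real_,
      n = length(values)
    )
  }
  median_range_row <- function(df, parameter, values) {
    tibble(
      analyte = df$analyte[1], parameter = parameter,
      summary_type = "median_range",
      mean = NA_real_, sd = NA_real_, cv = NA_real_,
      median = median(values), range_low = min(values),
      range_high = max(values), n = length(values)
    )
  }
  parameters <- params %>%
    group_by(.data$analyte) %>%
    dplyr::group_modify(function(df, key) {
      df$analyte <- key$analyte
      rows <- list(
        mean_sd_row(df, "auc_0_t", df$auc_0_t),
        mean_sd_row(df, "cmax", df$cmax),
        median_range_row(df, "tmax", df$tmax)
      )
      with2 <- df[df$cmax2_detected, , drop = FALSE]
      if (nrow(with2) > 0) {
        rows <- c(rows, list(
          mean_sd_row(with2, "cmax2", with2$cmax2),
          median_range_row(with2, "tmax2", with2$tmax2)
        ))
      }
      bind_rows(rows) %>% select(-"analyte")
    }) %>%
    ungroup()

  structure(
    list(
      timepoints = timepoints,
      parameters = parameters,
      n = dplyr::n_distinct(params$subject_id),
      n_with_cmax2 = sum(params$cmax2_detected[params$analyte == "MPA"])
    ),
    class = "cohort_summary"
  )
}

#' @export
print.cohort_summary <- function(x, ...) {
  writeLines(report_text(x))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.cohort_summary <- function(x, ...) x$parameters

#' @exportS3Method generics::glance
glance.cohort_summary <- function(x, ...) {
  tibble(n = x$n, n_with_cmax2 = x$n_with_cmax2,
         n_timepoints = dplyr::n_distinct(x$timepoints$time_h))
}

#' Plot concentration-time profiles
#'
#' Spaghetti plot of individual profiles by analyte, on the study grid.
#'
#' @param profiles A profile table.
#' @return A ggplot object.
#' @export
plot_profiles <- function(profiles) {
  ggplot2::ggplot(
    as_tibble(profiles),
    ggplot2::aes(x = .data$time_h, y = .data$conc,
                 group = .data$subject_id, colour = .data$subject_id)
  ) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~analyte, scales = "free_y") +
    ggplot2::labs(x = "Time after dose (h)", y = "Concentration (ng/mL)") +
    ggplot2::guides(colour = "none") +
    ggplot2::theme_minimal()
}
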