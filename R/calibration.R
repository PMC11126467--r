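#' Instrument response of an injection
#'
#' For MPA the response is the analyte peak area divided by the internal
#' standard peak area (`is_ratio`); for MPAG the raw analyte peak area is
#' used (`raw_area`), because a deuterated glucuronide IS interferes at the
#' parent's transition. Vectorized over areas.
#'
#' @param analyte_area Analyte peak area(s), >= 0.
#' @param is_area Internal-standard peak area(s); required and strictly
#'   positive in `is_ratio` mode.
#' @param mode `"is_ratio"` or `"raw_area"`.
#' @return Numeric response(s), dimensionless in ratio mode.
#' @examples
#' compute_response(500, 1000, "is_ratio")  # 0.5
#' compute_response(500, mode = "raw_area") # 500
#' @export
compute_response <- function(analyte_area, is_area = NULL,
                             mode = c("is_ratio", "raw_area")) {
  mode <- match.arg(mode)
  if (any(analyte_area < 0, na.rm = TRUE)) abort("Peak areas must be >= 0.")
  if (mode == "raw_area") return(as.numeric(analyte_area))
  if (is.null(is_area) || any(is.na(is_area)) || any(is_area <= 0)) {
    abort("Signal-quality error: IS area absent or non-positive in is_ratio mode.")
  }
  as.numeric(analyte_area) / as.numeric(is_area)
}

#' Fit a calibration curve
#'
#' Fits the response/concentration relationship over the calibrated range
#' by unweighted ordinary least squares. Two model forms are available:
#'
#' * `linear`: `response = a * conc + b`, fitted on the raw scale;
#' * `power`: `response = alpha * conc^beta`, fitted as a straight line of
#'   `log(response)` on `log(conc)` and reported as `alpha =
#'   exp(intercept)`, `beta = slope`.
#'
#' The correlation coefficient `r` is computed on the fitted scale (log-log
#' for the power model). For the linear model the intercept is tested
#' against zero with a Student's t-test on `n - 2` degrees of freedom
#' (a non-significant intercept supports linearity through the origin).
#'
#' @param standards A data frame with columns `nominal_conc` (ng/mL, > 0)
#'   and `response` (>= 0), typically one row per calibration standard.
#' @param model `"linear"` (default) or `"power"`.
#' @param config An [analysis_config()]; supplies the calibrated range.
#' @param analyte Analyte label stored on the curve.
#' @param response_mode Response definition stored on the curve.
#'
#' @return An object of class `calibration_curve` with elements
#'   `analyte`, `response_mode`, `model`, `coefficients`, `r`, `range`,
#'   `n_points` and `intercept_test`. Supports [predict()],
#'   [tidy()], [glance()] and [autoplot()].
#' @examples
#' std <- tibble::tibble(
#'   nominal_conc = c(2, 5, 10, 20, 50, 100, 200, 500),
#'   response = 0.01 * nominal_conc
#' )
#' fit_calibration(std)
#' @export
fit_calibration <- function(standards, model = c("linear", "power"),
                            config = analysis_config(), analyte = "MPA",
                            response_mode = NULL) {
  model <- match.arg(model)
  standards <- as_tibble(standards)
  if (!all(c("nominal_conc", "response") %in% names(standards))) {
    abort("`standards` needs columns nominal_conc and response.")
  }
  x <- standards$nominal_conc
  y <- standards$response
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    abort("Calibration standards must be finite.")
  }
  if (any(x <= 0) || any(y < 0)) {
    abort("Nominal concentrations must be > 0 and responses >= 0.")
  }
  n_levels <- length(unique(x))
  if (n_levels < 6) {
    abort("Insufficient calibration: at least 6 distinct levels are required.")
  }
  if (any(x < config$lloq) || any(x > config$uloq)) {
    abort("Calibration standards must lie within [lloq, uloq].")
  }
  response_mode <- response_mode %||%
    unname(config$response_modes[analyte]) %||% "is_ratio"

  if (model == "linear") {
    fit <- lm(y ~ x)
    cf <- coef(fit)
    a <- unname(cf[2]); b <- unname(cf[1])
    if (a == 0) abort("Degenerate calibration: zero slope is not invertible.")
    se_b <- suppressWarnings(summary(fit))$coefficients[1, 2]
    tstat <- b / se_b
    df <- length(x) - 2
    pval <- 2 * pt(-abs(tstat), df)
    coefficients <- c(a = a, b = b)
    r <- stats::cor(x, y)
    intercept_test <- list(t = tstat, df = df, p_value = pval,
                           significant = pval < 0.05)
  } else {
    if (any(y <= 0)) {
      abort("Power model requires strictly positive responses at every standard.")
    }
    fit <- lm(log(y) ~ log(x))
    cf <- coef(fit)
    alpha <- exp(unname(cf[1])); beta <- unname(cf[2])
    if (beta == 0) abort("Degenerate calibration: zero exponent is not invertible.")
    se_b <- suppressWarnings(summary(fit))$coefficients[1, 2]
    tstat <- unname(cf[1]) / se_b
    df <- length(x) - 2
    pval <- 2 * pt(-abs(tstat), df)
    coefficients <- c(alpha = alpha, beta = beta)
    r <- stats::cor(log(x), log(y))
    intercept_test <- list(t = tstat, df = df, p_value = pval,
                           significant = pval < 0.05)
  }

  structure(
    list(
      analyte = analyte,
      response_mode = response_mode,
      model = model,
      coefficients = coefficients,
      r = r,
      range = c(lloq = config$lloq, uloq = config$uloq),
      n_points = length(x),
      intercept_test = intercept_test,
      standards = tibble(nominal_conc = x, response = y)
    ),
    class = "calibration_curve"
  )
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat("Calibration curve:", x$analyte, paste0("(", x$response_mode, ")"), "\n")
  if (x$model == "linear") {
    cat(sprintf("  response = %.6g * conc + %.6g\n",
                x$coefficients["a"], x$coefficients["b"]))
  } else {
    cat(sprintf("  response = %.6g * conc^%.6g\n",
                x$coefficients["alpha"], x$coefficients["beta"]))
  }
  cat(sprintf("  r = %.5f over %g-%g ng/mL (%d points)\n",
              x$r, x$range["lloq"], x$range["uloq"], x$n_points))
  if (x$model == "linear") {
    cat(sprintf("  intercept t = %.3f (p = %.4g): %s\n",
                x$intercept_test$t, x$intercept_test$p_value,
                if (x$intercept_test$significant) "significant" else
                  "not significant"))
  }
  invisible(x)
}

#' Predicted response at given concentrations
#'
#' @param object A `calibration_curve`.
#' @param conc Concentrations (ng/mL).
#' @param ... Unused.
#' @return Predicted responses.
#' @export
predict.calibration_curve <- function(object, conc, ...) {
  cf <- object$coefficients
  if (object$model == "linear") {
    unname(cf["a"] * conc + cf["b"])
  } else {
    unname(cf["alpha"] * conc^cf["beta"])
  }
}

#' @exportS3Method generics::tidy
tidy.calibration_curve <- function(x, ...) {
  tibble(
    analyte = x$analyte,
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    model = x$model
  )
}

#' @exportS3Method generics::glance
glance.calibration_curve <- function(x, ...) {
  tibble(
    analyte = x$analyte,
    model = x$model,
    response_mode = x$response_mode,
    r = x$r,
    n_points = x$n_points,
    lloq = unname(x$range["lloq"]),
    uloq = unname(x$range["uloq"]),
    intercept_t = x$intercept_test$t,
    intercept_p = x$intercept_test$p_value,
    intercept_significant = x$intercept_test$significant
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.calibration_curve <- function(object, ...) {
  grid <- tibble(
    nominal_conc = seq(object$range["lloq"], object$range["uloq"],
                       length.out = 200)
  )
  grid$response <- predict(object, grid$nominal_conc)
  ggplot2::ggplot(object$standards,
                  ggplot2::aes(x = .data$nominal_conc, y = .data$response)) +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "Nominal concentration (ng/mL)",
      y = if (object$response_mode == "is_ratio") "Area ratio (analyte/IS)"
          else "Peak area",
      title = paste0(object$analyte, " calibration (", object$model, ")")
    ) +
    ggplot2::theme_minimal()
}

#' Back-calculate concentration from response
#'
#' Inverts the calibration model: `(response - b)/a` for the linear form,
#' `(response/alpha)^(1/beta)` for the power form. Values below the LLOQ
#' are flagged `blq` (a negative inverse is clipped to 0), values above the
#' ULOQ are flagged `aloq`. Vectorized over responses.
#'
#' @param curve A `calibration_curve`.
#' @param response Responses, >= 0.
#' @return A tibble with columns `conc` (ng/mL) and `flag`
#'   (`ok`/`blq`/`aloq`).
#' @export
back_calculate <- function(curve, response) {
  if (!inherits(curve, "calibration_curve")) {
    abort("`curve` must be a calibration_curve.")
  }
  if (any(response < 0, na.rm = TRUE)) abort("Responses must be >= 0.")
  cf <- curve$coefficients
  conc <- if (curve$model == "linear") {
    unname((response - cf["b"]) / cf["a"])
  } else {
    unname((pmax(response, 0) / cf["alpha"])^(1 / cf["beta"]))
  }
  flag <- dplyr::case_when(
    conc < 0 ~ "blq",
    conc < curve$range["lloq"] ~ "blq",
    conc > curve$range["uloq"] ~ "aloq",
    TRUE ~ "ok"
  )
  tibble(conc = pmax(conc, 0), flag = flag)
}

#' Back-calculation accuracy of the calibration standards
#'
#' Back-calculates each standard through the fitted curve and expresses it
#' as a percent of nominal. The curve passes when every level is within
#' +/- 15% of nominal, except the LLOQ where +/- 20% applies (both bounds
#' inclusive).
#'
#' @param curve A `calibration_curve`.
#' @param standards The standards the curve was fitted on.
#' @param criteria An [acceptance_criteria()].
#' @return A tibble with one row per standard (`nominal_conc`,
#'   `back_calculated`, `accuracy`, `tolerance_low`, `tolerance_high`,
#'   `pass`) carrying an attribute `pass` with the overall verdict.
#' @export
evaluate_calibration <- function(curve, standards,
                                 criteria = acceptance_criteria()) {
  standards <- as_tibble(standards)
  bc <- back_calculate(curve, standards$response)
  lloq <- unname(curve$range["lloq"])
  is_lloq <- standards$nominal_conc == lloq
  out <- tibble(
    nominal_conc = standards$nominal_conc,
    back_calculated = bc$conc,
    accuracy = bc$conc / standards$nominal_conc * 100,
    tolerance_low = ifelse(is_lloq, criteria$acc_low_lloq, criteria$acc_low),
    tolerance_high = ifelse(is_lloq, criteria$acc_high_lloq, criteria$acc_high)
  ) %>%
    mutate(pass = .data$accuracy >= .data$tolerance_low &
             .data$accuracy <= .data$tolerance_high)
  attr(out, "pass") <- all(out$pass)
  out
}

#' Correct a measured concentration for sample dilution
#'
#' Multiplies the back-calculated concentration of a diluted sample by its
#' dilution factor (e.g. an over-range sample diluted twofold with blank
#' saliva measures 400 ng/mL and reports 800 ng/mL).
#'
#' @param conc Measured concentration(s) (ng/mL, >= 0).
#' @param factor Dilution factor(s), >= 1.
#' @return Corrected concentration(s).
#' @export
apply_dilution <- function(conc, factor) {
  if (any(conc < 0, na.rm = TRUE)) abort("Concentrations must be >= 0.")
  if (any(factor < 1, na.rm = TRUE)) abort("Dilution factor must be >= 1.")
  conc * factor
}

#' Quantify a run table against fitted calibration curves
#'
#' Computes each record's response under its analyte's response mode,
#' back-calculates through that analyte's curve, and applies the record's
#' dilution factor after back-calculation. Blank records carry no
#' concentration and are excluded (their responses are reported by the
#' validation battery instead). A record is flagged `blq` when the
#' back-calculated value falls below the LLOQ, and `aloq` when it exceeds
#' the ULOQ without a dilution factor; a diluted record whose corrected
#' value is in range is `ok`.
#'
#' @param table A [run_table()].
#' @param curves Named list of `calibration_curve`s, one per analyte
#'   present.
#' @param config An [analysis_config()].
#' @return A tibble with one row per non-blank record: identifiers, the
#'   computed `response`, `measured_conc` (dilution-corrected, ng/mL),
#'   `flag`, and `dilution_applied`.
#' @export
quantify_run <- function(table, curves, config = analysis_config()) {
  records <- as_tibble(table)
  analytes <- unique(records$analyte[records$role != "blank"])
  missing_curves <- setdiff(analytes, names(curves))
  if (length(missing_curves) > 0) {
    abort(paste0("No calibration curve supplied for analyte(s): ",
                 paste(missing_curves, collapse = ", "), "."))
  }
  records %>%
    filter(.data$role != "blank") %>%
    group_by(.data$analyte) %>%
    dplyr::group_modify(function(df, key) {
      curve <- curves[[key$analyte]]
      response <- compute_response(df$analyte_area, df$is_area,
                                   mode = curve$response_mode)
      bc <- back_calculate(curve, response)
      measured <- apply_dilution(bc$conc, df$dilution_factor)
      flag <- dplyr::case_when(
        bc$flag == "blq" ~ "blq",
        bc$flag == "aloq" & df$dilution_factor == 1 ~ "aloq",
        TRUE ~ "ok"
      )
      tibble(
        sample_id = df$sample_id,
        role = df$role,
        nominal_conc = df$nominal_conc,
        run_id = df$run_id,
        matrix_id = df$matrix_id,
        condition = df$condition,
        injection_order = df$injection_order,
        response = response,
        measured_conc = measured,
        flag = flag,
        dilution_applied = df$dilution_factor
      )
    }) %>%
    ungroup() %>%
    arrange(.data$run_id, .data$injection_order) %>%
    select(
      "sample_id", "role", "analyte", "nominal_conc", "run_id", "matrix_id",
      "condition", "injection_order", "response", "measured_conc", "flag",
      "dilution_applied"
    )
}
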