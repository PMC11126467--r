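#' Paired measurements of the same samples by two methods
#'
#' @param pairs A data frame with numeric columns `reference` (the new
#'   method) and `comparator` (the method being compared against it), one
#'   row per sample.
#' @param min_n Minimum number of pairs.
#' @return The validated tibble.
#' @keywords internal
check_pairs <- function(pairs, min_n = 3) {
  pairs <- as_tibble(pairs)
  if (!all(c("reference", "comparator") %in% names(pairs))) {
    abort("`pairs` needs columns `reference` and `comparator`.")
  }
  if (nrow(pairs) < min_n) {
    abort(paste0("At least ", min_n, " pairs are required."))
  }
  if (any(!is.finite(pairs$reference)) || any(!is.finite(pairs$comparator))) {
    abort("Paired measurements must be finite.")
  }
  pairs
}

#' Bland-Altman agreement analysis
#'
#' Differences are `comparator - reference`, so a comparator method that
#' reads systematically lower yields a negative mean difference. Limits of
#' agreement are `mean +/- 1.96 * SD` of the differences (n-1 SD); the 95%
#' CI of the mean difference uses the t distribution on n-1 degrees of
#' freedom. Agreement is flagged "erratic" when more than 5% of the points
#' fall outside the limits of agreement, and the line of equality is judged
#' by whether 0 lies inside the CI of the mean difference.
#'
#' @param pairs A data frame with columns `reference` and `comparator`.
#' @param conf_level Confidence level for the mean-difference CI.
#' @param criteria An [acceptance_criteria()]; supplies the tolerated
#'   fraction outside the limits.
#' @return An object of class `bland_altman` with elements `mean_diff`,
#'   `sd_diff`, `loa_low`, `loa_high`, `ci_mean_diff`, `n_outside`,
#'   `prop_outside`, `equality_in_ci`, `erratic_flag`, `n`, `differences`.
#' @export
bland_altman <- function(pairs, conf_level = 0.95,
                         criteria = acceptance_criteria()) {
  pairs <- check_pairs(pairs)
  d <- pairs$comparator - pairs$reference
  n <- length(d)
  m <- mean(d)
  s <- sd(d)
  loa_low <- m - 1.96 * s
  loa_high <- m + 1.96 * s
  tq <- qt(1 - (1 - conf_level) / 2, df = n - 1)
  ci <- c(m - tq * s / sqrt(n), m + tq * s / sqrt(n))
  outside <- d < loa_low | d > loa_high
  structure(
    list(
      mean_diff = m, sd_diff = s,
      loa_low = loa_low, loa_high = loa_high,
      ci_mean_diff = ci,
      n_outside = sum(outside),
      prop_outside = mean(outside),
      equality_in_ci = ci[1] <= 0 && 0 <= ci[2],
      erratic_flag = mean(outside) > criteria$outside_loa_max,
      n = n,
      pairs = pairs,
      differences = d
    ),
    class = "bland_altman"
  )
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf(
    "Bland-Altman (n = %d): mean difference %.4g [%.4g, %.4g], LoA %.4g to %.4g\n",
    x$n, x$mean_diff, x$ci_mean_diff[1], x$ci_mean_diff[2],
    x$loa_low, x$loa_high
  ))
  cat(sprintf("  %d point(s) (%.1f%%) outside the limits%s\n",
              x$n_outside, 100 * x$prop_outside,
              if (x$erratic_flag) " -> erratic variability" else ""))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.bland_altman <- function(x, ...) {
  tibble(
    mean_diff = x$mean_diff, sd_diff = x$sd_diff,
    loa_low = x$loa_low, loa_high = x$loa_high,
    ci_low = x$ci_mean_diff[1], ci_high = x$ci_mean_diff[2],
    n_outside = x$n_outside, prop_outside = x$prop_outside,
    equality_in_ci = x$equality_in_ci, erratic_flag = x$erratic_flag,
    n = x$n
  )
}

#' @exportS3Method generics::glance
glance.bland_altman <- function(x, ...) tidy(x)

#' @exportS3Method ggplot2::autoplot
autoplot.bland_altman <- function(object, ...) {
  df <- tibble(
    mean_of_pair = (object$pairs$reference + object$pairs$comparator) / 2,
    difference = object$differences
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean_of_pair,
                                   y = .data$difference)) +
    ggplot2::geom_hline(yintercept = object$mean_diff, colour = "steelblue") +
    ggplot2::geom_hline(yintercept = c(object$loa_low, object$loa_high),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Mean of methods (ng/mL)",
                  y = "Difference, comparator - reference (ng/mL)",
                  title = "Bland-Altman plot") +
    ggplot2::theme_minimal()
}

#' Passing-Bablok regression
#'
#' Nonparametric method-comparison regression from the classical
#' pairwise-slope procedure: all slopes `S_ij = (y_j - y_i)/(x_j - x_i)`
#' over pairs `i < j` are computed; pairs tied in both coordinates
#' contribute nothing, pairs tied only in `x` contribute a signed infinite
#' slope at the end of the sort, and slopes exactly equal to -1 are
#' discarded. With `K` the number of slopes below -1, the slope estimate is
#' the median of the sorted slopes shifted by `K`; the confidence bounds
#' sit at rank offsets derived from the normal approximation
#' `w = z * sqrt(n (n-1) (2n+5) / 18)`. The intercept is
#' `median(y - slope * x)`, with its CI obtained from the slope bounds the
#' same way. A slope CI excluding 1 indicates proportional bias; an
#' intercept CI excluding 0 indicates constant bias.
#'
#' @param pairs A data frame with columns `reference` (x) and `comparator`
#'   (y).
#' @param alpha Two-sided significance level for the CIs (default 0.05).
#' @return An object of class `passing_bablok` with `slope`, `slope_ci`,
#'   `intercept`, `intercept_ci`, `n_slopes_used`, `proportional_bias`,
#'   `constant_bias`, `n`.
#' @examples
#' pb <- passing_bablok(tibble::tibble(reference = 1:5,
#'                                     comparator = 2 * (1:5) + 1))
#' pb$slope # 2
#' @export
passing_bablok <- function(pairs, alpha = 0.05) {
  pairs <- check_pairs(pairs)
  x <- pairs$reference
  y <- pairs$comparator
  n <- length(x)
  if (length(unique(x)) == 1) {
    abort("Degenerate input: all reference values identical.")
  }
  ij <- utils::combn(n, 2)
  dx <- x[ij[2, ]] - x[ij[1, ]]
  dy <- y[ij[2, ]] - y[ij[1, ]]
  both_tied <- dx == 0 & dy == 0
  dx <- dx[!both_tied]
  dy <- dy[!both_tied]
  slopes <- ifelse(dx == 0, sign(dy) * Inf, dy / dx)
  slopes <- slopes[slopes != -1]
  N <- length(slopes)
  if (N == 0) abort("No usable pairwise slopes.")
  slopes <- sort(slopes) # Inf sorts to the ends
  K <- sum(slopes < -1)

  shifted_median <- function(s, K) {
    N <- length(s)
    if (N %% 2 == 1) {
      s[(N + 1) / 2 + K]
    } else {
      (s[N / 2 + K] + s[N / 2 + 1 + K]) / 2
    }
  }
  slope <- shifted_median(slopes, K)

  z <- qnorm(1 - alpha / 2)
  w <- z * sqrt(n * (n - 1) * (2 * n + 5) / 18)
  m1 <- floor((N - w) / 2)
  lo_idx <- min(max(m1 + K, 1), N)
  hi_idx <- min(max(N - m1 + 1 + K, 1), N)
  slope_ci <- c(slopes[lo_idx], slopes[hi_idx])

  intercept <- median(y - slope * x)
  intercept_ci <- c(median(y - slope_ci[2] * x), median(y - slope_ci[1] * x))

  structure(
    list(
      slope = slope, slope_ci = slope_ci,
      intercept = intercept, intercept_ci = sort(intercept_ci),
      n_slopes_used = N,
      proportional_bias = !(slope_ci[1] <= 1 && 1 <= slope_ci[2]),
      constant_bias = !(min(intercept_ci) <= 0 && 0 <= max(intercept_ci)),
      n = n,
      pairs = pairs
    ),
    class = "passing_bablok"
  )
}

#' @export
print.passing_bablok <- function(x, ...) {
  cat(sprintf("Passing-Bablok (n = %d, %d slopes):\n", x$n, x$n_slopes_used))
  cat(sprintf("  slope %.4f (95%% CI %.4f to %.4f)%s\n",
              x$slope, x$slope_ci[1], x$slope_ci[2],
              if (x$proportional_bias) " -> proportional bias" else ""))
  cat(sprintf("  intercept %.4f (95%% CI %.4f to %.4f)%s\n",
              x$intercept, x$intercept_ci[1], x$intercept_ci[2],
              if (x$constant_bias) " -> constant bias" else ""))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.passing_bablok <- function(x, ...) {
  tibble(
    term = c("slope", "intercept"),
    estimate = c(x$slope, x$intercept),
    conf_low = c(x$slope_ci[1], x$intercept_ci[1]),
    conf_high = c(x$slope_ci[2], x$intercept_ci[2])
  )
}

#' @exportS3Method generics::glance
glance.passing_bablok <- function(x, ...) {
  tibble(
    slope = x$slope, intercept = x$intercept,
    proportional_bias = x$proportional_bias,
    constant_bias = x$constant_bias,
    n = x$n, n_slopes_used = x$n_slopes_used
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.passing_bablok <- function(object, ...) {
  ggplot2::ggplot(object$pairs,
                  ggplot2::aes(x = .data$reference, y = .data$comparator)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Reference method (ng/mL)",
                  y = "Comparator method (ng/mL)",
                  title = "Passing-Bablok regression") +
    ggplot2::theme_minimal()
}

#' Pearson correlation of paired measurements
#'
#' Product-moment correlation with a two-sided p-value from the exact t
#' transform `t = r * sqrt(n - 2) / sqrt(1 - r^2)` on n-2 degrees of
#' freedom.
#'
#' @param pairs A data frame with columns `reference` and `comparator`.
#' @return An object of class `pearson_correlation` with `r`, `p_value`,
#'   `n`.
#' @export
pearson_correlation <- function(pairs) {
  pairs <- check_pairs(pairs)
  x <- pairs$reference
  y <- pairs$comparator
  if (sd(x) == 0 || sd(y) == 0) {
    abort("Degenerate input: zero variance in one series.")
  }
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  p <- if (abs(r) == 1) 0 else {
    tstat <- r * sqrt(n - 2) / sqrt(1 - r^2)
    2 * pt(-abs(tstat), df = n - 2)
  }
  structure(list(r = r, p_value = p, n = n), class = "pearson_correlation")
}

#' @export
print.pearson_correlation <- function(x, ...) {
  cat(sprintf("Pearson r = %.4f (n = %d, p = %s)\n", x$r, x$n,
              format.pval(x$p_value, digits = 4)))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.pearson_correlation <- function(x, ...) {
  tibble(r = x$r, p_value = x$p_value, n = x$n)
}

#' Shapiro-Wilk normality test
#'
#' Thin wrapper around [stats::shapiro.test()], used to justify the choice
#' of Pearson correlation for the method comparison.
#'
#' @param values Numeric sample, 3 <= n <= 5000 and not constant.
#' @return A tibble with `statistic` (W) and `p_value`.
#' @export
normality_test <- function(values) {
  if (length(values) < 3 || length(values) > 5000) {
    abort("Shapiro-Wilk requires 3 <= n <= 5000.")
  }
  if (sd(values) == 0) {
    abort("Degenerate input: constant sample has no defined W statistic.")
  }
  ht <- shapiro.test(values)
  tibble(statistic = unname(ht$statistic), p_value = ht$p.value)
}

#' Full method-comparison analysis
#'
#' Runs the Bland-Altman analysis, Passing-Bablok regression, Pearson
#' correlation, and Shapiro-Wilk normality checks of both series on one
#' set of paired measurements.
#'
#' @param pairs A data frame with columns `reference` and `comparator`.
#' @param criteria An [acceptance_criteria()].
#' @return An object of class `agreement_result` with elements
#'   `bland_altman`, `passing_bablok`, `pearson`, `normality`, `n`.
#' @export
compare_methods <- function(pairs, criteria = acceptance_criteria()) {
  pairs <- check_pairs(pairs)
  structure(
    list(
      bland_altman = bland_altman(pairs, criteria = criteria),
      passing_bablok = passing_bablok(pairs),
      pearson = pearson_correlation(pairs),
      normality = list(
        reference = normality_test(pairs$reference),
        comparator = normality_test(pairs$comparator)
      ),
      n = nrow(pairs)
    ),
    class = "agreement_result"
  )
}

#' @export
print.agreement_result <- function(x, ...) {
  writeLines(report_text(x))
  invisible(x)
}
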