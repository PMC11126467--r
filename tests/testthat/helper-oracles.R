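# Independent oracles, deliberately coded differently from the package:
# plain loops and closed forms, no shared helpers.

# Ordinary least squares through the normal equations, solved directly.
ols_oracle <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  c(intercept = beta[1], slope = beta[2])
}

# Trapezoid AUC as an explicit loop.
trapz_oracle <- function(t, c) {
  s <- 0
  for (i in seq_len(length(t) - 1)) {
    s <- s + (t[i + 1] - t[i]) * (c[i] + c[i + 1]) / 2
  }
  s
}

# Passing-Bablok slope/intercept by brute-force enumeration of every
# pairwise slope (double loop), following the classical shifted-median
# definition.
pb_oracle <- function(x, y) {
  n <- length(x)
  slopes <- c()
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      dx <- x[j] - x[i]
      dy <- y[j] - y[i]
      if (dx == 0 && dy == 0) next
      s <- if (dx == 0) sign(dy) * Inf else dy / dx
      if (s == -1) next
      slopes <- c(slopes, s)
    }
  }
  slopes <- sort(slopes)
  N <- length(slopes)
  K <- length(slopes[slopes < -1])
  est <- if (N %% 2 == 1) {
    slopes[(N + 1) / 2 + K]
  } else {
    (slopes[N / 2 + K] + slopes[N / 2 + 1 + K]) / 2
  }
  list(slope = est, intercept = median(y - est * x), n_slopes = N)
}

# Pearson r straight from the covariance formula.
pearson_oracle <- function(x, y) {
  mean((x - mean(x)) * (y - mean(y))) / (sd(x) * sd(y)) * length(x) /
    (length(x) - 1)
}

# Mean MPA and MPAG cohort profiles as published (time, concentration).
published_mpa_profile <- function() {
  tibble::tibble(
    time_h = c(0, 1, 2, 3, 4, 6, 9, 12),
    conc = c(44.2, 145.6, 53.8, 37.0, 29.8, 21.6, 24.7, 36.9)
  )
}
published_mpag_profile <- function() {
  tibble::tibble(
    time_h = c(0, 1, 2, 3, 4, 6, 9, 12),
    conc = c(52.6, 67.6, 86.0, 75.1, 60.1, 50.3, 44.5, 28.9)
  )
}
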