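# Independent oracles used against the package implementations.
# These are written as direct transcriptions of the defining rules
# (explicit loops, full enumeration), deliberately sharing no code with
# the package.

# Passing-Bablok by full enumeration: all pairwise slopes, ties in both
# coordinates dropped, x-ties with differing y as +/-Inf, slopes of
# exactly -1 dropped, median rank shifted by K = #(slopes < -1); CI at
# ranks round((N - C)/2) + K and N - M1 + 1 + K.
pb_oracle <- function(x, y, level = 0.95) {
  n <- length(x)
  slopes <- numeric(0)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      dx <- x[j] - x[i]
      dy <- y[j] - y[i]
      if (dx == 0 && dy == 0) next
      s <- if (dx == 0) (if (dy > 0) Inf else -Inf) else dy / dx
      if (s == -1) next
      slopes <- c(slopes, s)
    }
  }
  slopes <- sort(slopes)
  N <- length(slopes)
  K <- sum(slopes < -1)
  b <- if (N %% 2 == 1) slopes[(N + 1) / 2 + K] else
    (slopes[N / 2 + K] + slopes[N / 2 + 1 + K]) / 2
  C <- qnorm((1 + level) / 2) * sqrt(n * (n - 1) * (2 * n + 5) / 18)
  M1 <- round((N - C) / 2)
  M2 <- N - M1 + 1
  clampi <- function(r) min(max(r, 1), N)
  list(slope = b,
       intercept = median(y - b * x),
       slope_ci = c(slopes[clampi(M1 + K)], slopes[clampi(M2 + K)]),
       n_slopes = N)
}

# Theil-Sen by full enumeration: median of finite pairwise slopes.
ts_oracle <- function(x, y, level = 0.95) {
  n <- length(x)
  slopes <- numeric(0)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (x[j] != x[i]) slopes <- c(slopes, (y[j] - y[i]) / (x[j] - x[i]))
    }
  }
  slopes <- sort(slopes)
  N <- length(slopes)
  b <- median(slopes)
  C <- qnorm((1 + level) / 2) * sqrt(n * (n - 1) * (2 * n + 5) / 18)
  M1 <- round((N - C) / 2)
  M2 <- N - M1 + 1
  clampi <- function(r) min(max(r, 1), N)
  list(slope = b, intercept = median(y - b * x),
       slope_ci = c(slopes[clampi(M1)], slopes[clampi(M2)]))
}

# Orthogonal (total least squares) line via the spectral route: the
# leading eigenvector of the covariance matrix of (x, y).
tls_oracle <- function(x, y) {
  v <- eigen(cov(cbind(x, y)), symmetric = TRUE)$vectors[, 1]
  b <- v[2] / v[1]
  list(slope = b, intercept = mean(y) - b * mean(x))
}

# ICC mean squares through stats::aov on the long layout, plus the
# McGraw-Wong forms computed from raw mean squares.
icc_oracle <- function(m) {
  n <- nrow(m); k <- ncol(m)
  long <- data.frame(score = as.vector(m),
                     subject = factor(rep(seq_len(n), k)),
                     rater = factor(rep(seq_len(k), each = n)))
  tw <- summary(aov(score ~ subject + rater, data = long))[[1]]
  msr <- tw["subject", "Mean Sq"]
  msc <- tw["rater", "Mean Sq"]
  mse <- tw["Residuals", "Mean Sq"]
  ow <- summary(aov(score ~ subject, data = long))[[1]]
  msw <- ow["Residuals", "Mean Sq"]
  list(
    msr = msr, msc = msc, mse = mse, msw = msw,
    oneway_single = (msr - msw) / (msr + (k - 1) * msw),
    cons_single = (msr - mse) / (msr + (k - 1) * mse),
    abs_single = (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n),
    oneway_avg = (msr - msw) / msr,
    cons_avg = (msr - mse) / msr,
    abs_avg = (msr - mse) / (msr + (msc - mse) / n)
  )
}

# Deterministic random pair fixture around a known line
make_line_pairs <- function(n, a = 0, b = 1, sd = 1, seed = 1,
                            xmin = 10, xmax = 100) {
  set.seed(seed)
  x <- runif(n, xmin, xmax)
  y <- a + b * x + rnorm(n, 0, sd)
  paired_measurements(x, y)
}
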