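#' @title Method-comparison regression estimators
#' @description Seven estimators of the line y = a + b x relating a test
#'   method to a reference method, each returning a common fit object so
#'   that bias assessment and reporting are estimator-agnostic.
#' @name mc-regression
NULL

new_mc_fit <- function(method, intercept, intercept_ci, slope, slope_ci,
                       n, options = list(), diagnostics = list()) {
  structure(
    list(method = method,
         intercept = intercept, intercept_ci = intercept_ci,
         slope = slope, slope_ci = slope_ci,
         n = n, options = options, diagnostics = diagnostics),
    class = "mc_fit"
  )
}

#' @export
print.mc_fit <- function(x, ...) {
  cat(sprintf("%s regression (n = %d)\n", x$method, x$n))
  cat(sprintf("  intercept: %.4f  [%.4f, %.4f]\n",
              x$intercept, x$intercept_ci[1], x$intercept_ci[2]))
  cat(sprintf("  slope:     %.4f  [%.4f, %.4f]\n",
              x$slope, x$slope_ci[1], x$slope_ci[2]))
  invisible(x)
}

#' Ordinary / weighted least squares
#'
#' OLS of y on x, optionally weighted. \code{weights = "inverse_x_squared"}
#' gives the proportional-error weighting 1/x^2 standard in method
#' comparison when the scatter grows with the measurement level; a numeric
#' vector of positive weights may be supplied instead. Confidence
#' intervals use Student t with n - 2 df.
#'
#' @param pairs A [paired_measurements()] object, n >= 3, x not constant.
#' @param weights \code{"none"}, \code{"inverse_x_squared"}, or a positive
#'   numeric vector of length n.
#' @param level Confidence level.
#' @return An \code{"mc_fit"} object (method \code{"ols"} or \code{"wols"}).
#' @export
fit_ols <- function(pairs, weights = "none", level = 0.95) {
  check_pairs(pairs, 3L, "least-squares regression")
  if (stats::sd(pairs$x) == 0) stop("x is constant; slope is undefined")
  dat <- data.frame(x = pairs$x, y = pairs$y)
  if (is.character(weights)) {
    weights <- match.arg(weights, c("none", "inverse_x_squared"))
    if (weights == "none") {
      w <- NULL
      method <- "ols"
      wspec <- "none"
    } else {
      if (any(pairs$x == 0)) {
        stop("inverse_x_squared weights require nonzero x values")
      }
      w <- 1 / pairs$x^2
      method <- "wols"
      wspec <- "inverse_x_squared"
    }
  } else {
    w <- as.numeric(weights)
    if (length(w) != pairs$n || any(!is.finite(w)) || any(w <= 0)) {
      stop("user weights must be a positive finite vector of length n")
    }
    method <- "wols"
    wspec <- "user"
  }
  fit <- if (is.null(w)) stats::lm(y ~ x, data = dat) else
    stats::lm(y ~ x, data = dat, weights = w)
  cf <- stats::coef(fit)
  ci <- stats::confint(fit, level = level)
  new_mc_fit(method,
             intercept = unname(cf[1]), intercept_ci = unname(ci[1, ]),
             slope = unname(cf[2]), slope_ci = unname(ci[2, ]),
             n = pairs$n,
             options = list(weights = wspec, level = level,
                            ci_method = "t"),
             diagnostics = list(sigma = summary(fit)$sigma,
                                slope_se = summary(fit)$coefficients[2, 2]))
}

# Closed-form Deming slope from (weighted) second moments.
# lambda = Var(err_x) / Var(err_y). Minimises
# sum w_i [ (x - xhat)^2 / lambda + (y - yhat)^2 ] (equivalently the
# errors-in-variables SSE with the weight on the y term equal to 1/lambda
# after rescaling), whose stationary slope is the positive root below.
deming_slope <- function(sxx, syy, sxy, lambda) {
  if (sxy == 0) {
    stop("covariance of x and y is zero: the Deming slope is undefined")
  }
  ((lambda * syy - sxx) +
      sqrt((lambda * syy - sxx)^2 + 4 * lambda * sxy^2)) /
    (2 * lambda * sxy)
}

deming_point <- function(x, y, lambda, weighted, w_tol = 1e-10,
                         max_iter = 100L) {
  wmom <- function(w) {
    sw <- sum(w)
    mx <- sum(w * x) / sw
    my <- sum(w * y) / sw
    list(mx = mx, my = my,
         sxx = sum(w * (x - mx)^2),
         syy = sum(w * (y - my)^2),
         sxy = sum(w * (x - mx) * (y - my)))
  }
  w <- rep(1, length(x))
  m <- wmom(w)
  b <- deming_slope(m$sxx, m$syy, m$sxy, lambda)
  a <- m$my - b * m$mx
  iters <- 0L
  if (weighted) {
    repeat {
      iters <- iters + 1L
      # fitted true values under the current line
      r <- y - a - b * x
      xhat <- x + lambda * b * r / (1 + lambda * b^2)
      if (any(xhat <= 0)) {
        stop("weighted Deming requires positive fitted true values ",
             "(weights are 1/xhat^2); data include nonpositive levels")
      }
      w <- 1 / xhat^2
      m <- wmom(w)
      b_new <- deming_slope(m$sxx, m$syy, m$sxy, lambda)
      a_new <- m$my - b_new * m$mx
      delta <- abs(b_new - b)
      b <- b_new
      a <- a_new
      if (delta < w_tol) break
      if (iters >= max_iter) {
        stop("weighted Deming did not converge in ", max_iter, " iterations")
      }
    }
  }
  list(intercept = a, slope = b, iterations = iters)
}

#' Deming errors-in-variables regression
#'
#' Fits y = a + b x allowing measurement error in both axes. The error
#' variance ratio \code{lambda} = Var(error in x) / Var(error in y)
#' fixes the direction in which deviations are measured: \code{lambda = 1}
#' (the default) is orthogonal regression; as \code{lambda -> 0} all error
#' is attributed to y and the fit tends to OLS of y on x; as
#' \code{lambda -> Inf} it tends to the inverse regression of x on y.
#' The minimised objective is the errors-in-variables sum of squares
#' sum\[(x_i - xhat_i)^2 + lambda (y_i - yhat_i)^2\] (up to the overall
#' 1/lambda factor, which does not move the minimiser).
#'
#' \code{weighted = TRUE} gives Linnet's iteratively reweighted variant
#' for proportional error: weights 1/xhat_i^2 recomputed from the current
#' fitted true values until the slope changes by < 1e-10 (at most 100
#' iterations).
#'
#' Confidence intervals default to the leave-one-out jackknife with a
#' t(n - 2) quantile; \code{ci_method = "analytic"} uses the normal-theory
#' approximation SE(b) = sqrt(b^2 (sxx syy / sxy^2 - 1) / (n - 2)).
#'
#' @param pairs A [paired_measurements()] object, n >= 3.
#' @param lambda Positive error variance ratio Var(err_x)/Var(err_y).
#' @param weighted Use Linnet's iterative reweighting.
#' @param level Confidence level.
#' @param ci_method \code{"jackknife"} (default) or \code{"analytic"}.
#' @return An \code{"mc_fit"} object (method \code{"deming"} or
#'   \code{"wdeming"}).
#' @examples
#' pm <- paired_measurements(c(0, 1, 2, 3), c(0.1, 0.9, 2.2, 2.9))
#' fit_deming(pm)
#' @export
fit_deming <- function(pairs, lambda = 1, weighted = FALSE, level = 0.95,
                       ci_method = c("jackknife", "analytic")) {
  check_pairs(pairs, 3L, "Deming regression")
  ci_method <- match.arg(ci_method)
  if (!is.finite(lambda) || lambda <= 0) stop("lambda must be positive")
  x <- pairs$x; y <- pairs$y; n <- pairs$n
  pt <- deming_point(x, y, lambda, weighted)
  tq <- stats::qt((1 + level) / 2, df = n - 2)
  if (ci_method == "jackknife") {
    loo <- vapply(seq_len(n), function(i) {
      p <- deming_point(x[-i], y[-i], lambda, weighted)
      c(p$intercept, p$slope)
    }, numeric(2))
    se <- sqrt((n - 1) / n * rowSums((loo - rowMeans(loo))^2))
    a_ci <- pt$intercept + c(-1, 1) * tq * se[1]
    b_ci <- pt$slope + c(-1, 1) * tq * se[2]
  } else {
    mx <- mean(x)
    sxx <- sum((x - mx)^2) / (n - 1)
    syy <- sum((y - mean(y))^2) / (n - 1)
    sxy <- sum((x - mx) * (y - mean(y))) / (n - 1)
    se_b <- sqrt(pt$slope^2 * (sxx * syy / sxy^2 - 1) / (n - 2))
    se_a <- se_b * sqrt(sum(x^2) / n)
    a_ci <- pt$intercept + c(-1, 1) * tq * se_a
    b_ci <- pt$slope + c(-1, 1) * tq * se_b
  }
  new_mc_fit(if (weighted) "wdeming" else "deming",
             intercept = pt$intercept, intercept_ci = a_ci,
             slope = pt$slope, slope_ci = b_ci, n = n,
             options = list(lambda = lambda, level = level,
                            ci_method = ci_method),
             diagnostics = list(iterations = pt$iterations))
}

# All pairwise slopes (y_j - y_i)/(x_j - x_i), i < j, as used by both the
# Passing-Bablok and Theil-Sen estimators. Pairs with dx == 0 get +/-Inf
# (sign of dy) or NaN when dy is also 0.
pairwise_slopes <- function(x, y) {
  n <- length(x)
  ij <- utils::combn(n, 2L)
  dx <- x[ij[2L, ]] - x[ij[1L, ]]
  dy <- y[ij[2L, ]] - y[ij[1L, ]]
  dy / dx
}

# Kendall's C_gamma rank half-width used by the distribution-free CIs
kendall_halfwidth <- function(n, level) {
  stats::qnorm((1 + level) / 2) * sqrt(n * (n - 1) * (2 * n + 5) / 18)
}

#' Passing-Bablok regression
#'
#' Rank-based, outlier-robust line fit. The slope is the shifted median
#' of all pairwise slopes S_ij = (y_j - y_i)/(x_j - x_i), i < j, following
#' the original 1983 rules: pairs identical in both coordinates contribute
#' nothing, ties in x with differing y contribute +/-Inf slopes, slopes
#' exactly equal to -1 are discarded, and the median rank is shifted by
#' K = #\{slopes < -1\} so that the estimator is invariant to swapping the
#' axes. The distribution-free confidence interval places the bounds at
#' ordered-slope ranks M1 + K and M2 + K with M1 = round((N - C)/2),
#' M2 = N - M1 + 1 and C = z sqrt(n(n-1)(2n+5)/18). The intercept is
#' median(y - b x), with its CI obtained from the slope CI endpoints.
#'
#' \code{large_mode = TRUE} computes the same estimator from a seeded
#' uniform random subsample of \code{min(N, max_pairs)} of the N = C(n,2)
#' pairs, with binomial rank bounds on the subsample in place of the exact
#' ranks — intended for datasets where enumerating all pairs is
#' impractical.
#'
#' @param pairs A [paired_measurements()] object; n >= 10 is recommended
#'   (a warning is issued below that, and whenever Kendall's tau is not
#'   positive, since the method presumes a positive association).
#' @param level Confidence level.
#' @param large_mode Subsample instead of full enumeration.
#' @param seed Integer seed, required when \code{large_mode = TRUE}.
#' @param max_pairs Subsample size cap for large mode (default 1e6).
#' @return An \code{"mc_fit"} object (method \code{"passing_bablok"} or
#'   \code{"pb_large"}); \code{diagnostics} records discarded-pair counts.
#' @export
fit_passing_bablok <- function(pairs, level = 0.95, large_mode = FALSE,
                               seed = NULL, max_pairs = 1e6) {
  check_pairs(pairs, 3L, "Passing-Bablok regression")
  x <- pairs$x; y <- pairs$y; n <- pairs$n
  if (n < 10L) {
    warning("Passing-Bablok regression is recommended for n >= 10 (n = ",
            n, ")")
  }
  tau <- suppressWarnings(stats::cor(x, y, method = "kendall"))
  if (is.finite(tau) && tau <= 0) {
    warning("Kendall's tau is not positive; Passing-Bablok assumes a ",
            "positive association between the methods")
  }

  if (!large_mode) {
    s_raw <- pairwise_slopes(x, y)
    n_identical <- sum(is.nan(s_raw))
    s <- s_raw[!is.nan(s_raw)]
    n_minus1 <- sum(s == -1)
    s <- s[s != -1]
    N <- length(s)
    if (N == 0L) stop("all pairwise slopes were discarded")
    s <- sort(s)                      # -Inf sorts first, +Inf last
    K <- sum(s < -1)
    b <- shifted_median(s, K)
    ci_idx <- pb_ci_ranks(N, kendall_halfwidth(n, level), K)
    b_ci <- c(s[ci_idx[1]], s[ci_idx[2]])
    diagnostics <- list(n_slopes = N, n_discarded_identical = n_identical,
                        n_discarded_minus_one = n_minus1, kendall_tau = tau)
    method <- "passing_bablok"
    opts <- list(level = level, ci_method = "rank")
  } else {
    if (is.null(seed)) stop("large_mode requires an integer seed")
    N_all <- n * (n - 1) / 2
    m <- min(N_all, max_pairs)
    idx <- if (m == N_all) seq_len(N_all) else
      withr::with_seed(seed, sample(N_all, m))
    ij <- decode_pair_index(idx, n)
    dx <- x[ij$j] - x[ij$i]
    dy <- y[ij$j] - y[ij$i]
    s_raw <- dy / dx
    n_identical <- sum(is.nan(s_raw))
    s <- s_raw[!is.nan(s_raw)]
    n_minus1 <- sum(s == -1)
    s <- s[s != -1]
    N <- length(s)
    if (N == 0L) stop("all sampled pairwise slopes were discarded")
    s <- sort(s)
    K <- sum(s < -1)
    b <- shifted_median(s, K)
    # binomial (normal-approximation) rank bounds for the median of the
    # subsampled slope set, shifted by K like the exact ranks
    half <- stats::qnorm((1 + level) / 2) * sqrt(N) / 2
    ci_idx <- pb_ci_ranks(N, 2 * half, K)
    b_ci <- c(s[ci_idx[1]], s[ci_idx[2]])
    diagnostics <- list(n_slopes = N, n_discarded_identical = n_identical,
                        n_discarded_minus_one = n_minus1,
                        subsampled = m < N_all, kendall_tau = tau)
    method <- "pb_large"
    opts <- list(level = level, ci_method = "binomial_rank", seed = seed,
                 max_pairs = max_pairs)
  }
  if (!all(is.finite(c(b, b_ci)))) {
    stop("Passing-Bablok slope or CI is not finite (too many ties in x)")
  }
  a <- stats::median(y - b * x)
  a_ci <- sort(c(stats::median(y - b_ci[2] * x),
                 stats::median(y - b_ci[1] * x)))
  new_mc_fit(method, intercept = a, intercept_ci = a_ci,
             slope = b, slope_ci = sort(b_ci), n = n,
             options = opts, diagnostics = diagnostics)
}

shifted_median <- function(s, K) {
  N <- length(s)
  if (N %% 2L == 1L) {
    s[(N + 1L) / 2L + K]
  } else {
    (s[N / 2L + K] + s[N / 2L + 1L + K]) / 2
  }
}

pb_ci_ranks <- function(N, C, K) {
  M1 <- round((N - C) / 2)
  M2 <- N - M1 + 1
  c(max(1L, min(N, M1 + K)), max(1L, min(N, M2 + K)))
}

# Decode linear pair indices t in 1..C(n,2) (ordered by i, then j > i)
# back to (i, j) without materialising all pairs.
decode_pair_index <- function(t, n) {
  t <- as.numeric(t)
  # cumulative pairs through row i: F(i) = i*n - i*(i+1)/2; find smallest
  # i with F(i) >= t via the quadratic inverse, then fix up
  i <- ceiling((2 * n - 1 - sqrt((2 * n - 1)^2 - 8 * t)) / 2)
  Fi <- i * n - i * (i + 1) / 2
  Fprev <- (i - 1) * n - (i - 1) * i / 2
  too_low <- Fi < t
  i[too_low] <- i[too_low] + 1
  too_high <- (i - 1) * n - (i - 1) * i / 2 >= t
  i[too_high] <- i[too_high] - 1
  Fprev <- (i - 1) * n - (i - 1) * i / 2
  j <- i + (t - Fprev)
  list(i = as.integer(i), j = as.integer(j))
}

#' Theil-Sen regression
#'
#' Nonparametric line fit: the slope is the plain median of all pairwise
#' slopes S_ij = (y_j - y_i)/(x_j - x_i), j > i, skipping pairs with tied
#' x. The intercept is median(y - b x). The slope confidence interval is
#' the standard distribution-free rank interval on the ordered slopes
#' using C = z sqrt(n(n-1)(2n+5)/18) (the Passing-Bablok construction
#' without the K offset); the intercept CI comes from the slope CI
#' endpoints.
#'
#' @param pairs A [paired_measurements()] object, n >= 3, x not all equal.
#' @param level Confidence level.
#' @return An \code{"mc_fit"} object (method \code{"theil_sen"}).
#' @examples
#' pm <- paired_measurements(c(0, 1, 2, 3), c(0, 2, 1, 3))
#' fit_theil_sen(pm)$slope  # 0.75
#' @export
fit_theil_sen <- function(pairs, level = 0.95) {
  check_pairs(pairs, 3L, "Theil-Sen regression")
  x <- pairs$x; y <- pairs$y; n <- pairs$n
  s <- pairwise_slopes(x, y)
  n_skipped <- sum(!is.finite(s))
  s <- sort(s[is.finite(s)])
  N <- length(s)
  if (N == 0L) stop("all x values are tied; the slope is undefined")
  b <- stats::median(s)
  ci_idx <- pb_ci_ranks(N, kendall_halfwidth(n, level), 0L)
  b_ci <- c(s[ci_idx[1]], s[ci_idx[2]])
  a <- stats::median(y - b * x)
  a_ci <- sort(c(stats::median(y - b_ci[2] * x),
                 stats::median(y - b_ci[1] * x)))
  new_mc_fit("theil_sen", intercept = a, intercept_ci = a_ci,
             slope = b, slope_ci = b_ci, n = n,
             options = list(level = level, ci_method = "rank"),
             diagnostics = list(n_slopes = N, n_skipped_tied_x = n_skipped))
}

#' Systematic and proportional bias flags from a regression fit
#'
#' Systematic (constant) bias is declared when the intercept confidence
#' interval excludes 0; proportional bias when the slope confidence
#' interval excludes 1.
#'
#' @param fit An \code{"mc_fit"} object with both confidence intervals.
#' @return An object of class \code{"bias_assessment"} with logical flags
#'   \code{systematic_bias}, \code{proportional_bias} and a
#'   \code{narrative} string.
#' @export
assess_bias <- function(fit) {
  stopifnot(inherits(fit, "mc_fit"))
  if (anyNA(fit$intercept_ci) || anyNA(fit$slope_ci)) {
    stop("the fit has no confidence intervals; bias cannot be assessed")
  }
  systematic <- fit$intercept_ci[1] > 0 || fit$intercept_ci[2] < 0
  proportional <- fit$slope_ci[1] > 1 || fit$slope_ci[2] < 1
  narrative <- if (systematic && proportional) {
    sprintf(paste0("Both systematic and proportional bias: the intercept CI ",
                   "[%.3f, %.3f] excludes 0 and the slope CI [%.3f, %.3f] ",
                   "excludes 1."),
            fit$intercept_ci[1], fit$intercept_ci[2],
            fit$slope_ci[1], fit$slope_ci[2])
  } else if (systematic) {
    sprintf(paste0("Systematic bias: the intercept CI [%.3f, %.3f] excludes ",
                   "0; no proportional bias (slope CI [%.3f, %.3f] ",
                   "includes 1)."),
            fit$intercept_ci[1], fit$intercept_ci[2],
            fit$slope_ci[1], fit$slope_ci[2])
  } else if (proportional) {
    sprintf(paste0("Proportional bias: the slope CI [%.3f, %.3f] excludes 1; ",
                   "no systematic bias (intercept CI [%.3f, %.3f] ",
                   "includes 0)."),
            fit$slope_ci[1], fit$slope_ci[2],
            fit$intercept_ci[1], fit$intercept_ci[2])
  } else {
    "No evidence of systematic or proportional bias between the methods."
  }
  structure(list(systematic_bias = systematic,
                 proportional_bias = proportional,
                 narrative = narrative),
            class = "bias_assessment")
}

#' @export
print.bias_assessment <- function(x, ...) {
  cat(x$narrative, "\n")
  invisible(x)
}

#' Recommend regression estimators from the assumption report
#'
#' Decision table: homoscedastic and outlier-free data support OLS and
#' Deming; heteroscedastic but outlier-free data call for their weighted
#' variants; once outliers are present only the rank-based estimators
#' (Passing-Bablok, Theil-Sen) are recommended, since weighting does not
#' defuse gross outliers. Above \code{large_threshold} subjects the
#' subsampling Passing-Bablok replaces the exact one.
#'
#' @param report An \code{"assumption_report"} from [run_assumptions()].
#' @param n Number of subjects.
#' @param large_threshold Subject count above which pb_large replaces
#'   passing_bablok (default 5000).
#' @return A list with \code{methods} (character vector, ranked) and
#'   \code{rationale} (named character vector, one line per method).
#' @export
select_method <- function(report, n, large_threshold = 5000) {
  stopifnot(inherits(report, "assumption_report"))
  hetero <- report$heteroscedastic
  outliers <- report$has_outliers
  if (outliers) {
    methods <- c("passing_bablok", "theil_sen")
    why <- paste0(report$outliers$n_flagged,
                  " multivariate outlier(s) flagged: only rank-based ",
                  "estimators are robust",
                  if (hetero) "; data are also heteroscedastic" else "")
    rationale <- c(passing_bablok = why,
                   theil_sen = "median-of-slopes estimator, robust to outliers")
  } else if (hetero) {
    methods <- c("wols", "wdeming")
    rationale <- c(
      wols = "heteroscedastic residuals: weighted least squares",
      wdeming = "heteroscedastic residuals with error in both methods: weighted Deming")
  } else {
    methods <- c("ols", "deming")
    rationale <- c(
      ols = "homoscedastic, outlier-free: ordinary least squares is valid",
      deming = "errors in both methods: Deming complements OLS")
  }
  if (n > large_threshold) {
    methods[methods == "passing_bablok"] <- "pb_large"
    names(rationale)[names(rationale) == "passing_bablok"] <- "pb_large"
    if ("pb_large" %in% names(rationale)) {
      rationale[["pb_large"]] <- paste0(rationale[["pb_large"]],
                                        " (subsampling mode for n > ",
                                        large_threshold, ")")
    }
  }
  list(methods = methods, rationale = rationale)
}

#' Fit one estimator by name
#'
#' Dispatch helper used by the pipeline and the command-line interface.
#'
#' @param pairs A [paired_measurements()] object.
#' @param method One of \code{"ols"}, \code{"wols"}, \code{"deming"},
#'   \code{"wdeming"}, \code{"passing_bablok"}, \code{"pb_large"},
#'   \code{"theil_sen"}.
#' @param level Confidence level.
#' @param lambda Deming error variance ratio.
#' @param seed Seed for \code{pb_large}.
#' @param max_pairs Subsample cap for \code{pb_large}.
#' @return An \code{"mc_fit"} object.
#' @export
fit_method <- function(pairs, method, level = 0.95, lambda = 1,
                       seed = NULL, max_pairs = 1e6) {
  switch(method,
    ols = fit_ols(pairs, "none", level),
    wols = fit_ols(pairs, "inverse_x_squared", level),
    deming = fit_deming(pairs, lambda, FALSE, level),
    wdeming = fit_deming(pairs, lambda, TRUE, level),
    passing_bablok = fit_passing_bablok(pairs, level),
    pb_large = fit_passing_bablok(pairs, level, large_mode = TRUE,
                                  seed = if (is.null(seed)) 1L else seed,
                                  max_pairs = max_pairs),
    theil_sen = fit_theil_sen(pairs, level),
    stop("unknown regression method: ", method)
  )
}
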