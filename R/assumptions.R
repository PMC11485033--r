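#' Normality check with automatic test choice
#'
#' Shapiro-Wilk for n <= 5000 (the test's implementation limit), otherwise
#' the Lilliefors-corrected Kolmogorov-Smirnov test (parameters are
#' estimated from the data, so the plain KS null distribution would be
#' anti-conservative).
#'
#' @param values Numeric vector, n >= 3, finite.
#' @param alpha Significance level used for the \code{is_normal} verdict.
#' @return A list with \code{test_name} (\code{"shapiro_wilk"} or
#'   \code{"kolmogorov_smirnov_lilliefors"}), \code{statistic},
#'   \code{p_value} and \code{is_normal} (\code{p >= alpha}).
#' @examples
#' check_normality(qnorm(ppoints(20)))
#' @export
check_normality <- function(values, alpha = 0.05) {
  values <- as.numeric(values)
  if (length(values) < 3L) stop("normality check requires n >= 3")
  if (!all(is.finite(values))) stop("values must be finite")
  if (stats::sd(values) == 0) {
    stop("degenerate input: values are constant (zero variance), ",
         "normality is undefined")
  }
  if (length(values) <= 5000L) {
    ht <- stats::shapiro.test(values)
    test_name <- "shapiro_wilk"
  } else {
    ht <- nortest::lillie.test(values)
    test_name <- "kolmogorov_smirnov_lilliefors"
  }
  list(test_name = test_name,
       statistic = unname(ht$statistic),
       p_value = ht$p.value,
       is_normal = ht$p.value >= alpha)
}

#' Association between differences and means
#'
#' Bland-Altman assumption check: correlates the per-subject differences
#' d = y - x with the per-subject means m = (x + y) / 2. Pearson's r is
#' used when both d and m pass [check_normality()] at \code{alpha},
#' otherwise Spearman's rho.
#'
#' @param pairs A [paired_measurements()] object, n >= 4.
#' @param alpha Significance level (for both the normality gate and the
#'   association verdict).
#' @param force_method Optional \code{"pearson"} or \code{"spearman"} to
#'   override the automatic choice.
#' @return A list with \code{method}, \code{coefficient}, \code{p_value}
#'   and \code{is_associated} (\code{p < alpha}).
#' @export
check_diff_mean_association <- function(pairs, alpha = 0.05,
                                        force_method = NULL) {
  check_pairs(pairs, 4L, "the difference-vs-mean association check")
  d <- pairs$y - pairs$x
  m <- (pairs$x + pairs$y) / 2
  if (stats::sd(d) == 0) {
    stop("degenerate input: differences are constant; ",
         "association with the mean is undefined")
  }
  if (stats::sd(m) == 0) {
    stop("degenerate input: per-subject means are constant")
  }
  if (is.null(force_method)) {
    both_normal <- check_normality(d, alpha)$is_normal &&
      check_normality(m, alpha)$is_normal
    method <- if (both_normal) "pearson" else "spearman"
  } else {
    method <- match.arg(force_method, c("pearson", "spearman"))
  }
  ct <- suppressWarnings(stats::cor.test(d, m, method = method,
                                         exact = FALSE))
  list(method = method,
       coefficient = unname(ct$estimate),
       p_value = ct$p.value,
       is_associated = ct$p.value < alpha)
}

#' Breusch-Pagan heteroscedasticity test
#'
#' Tests whether the residual variance of the OLS regression of y on x
#' depends on x. The default is the studentized (Koenker) variant, which
#' is robust to non-normal errors; \code{studentized = FALSE} gives the
#' original Breusch-Pagan statistic. The LM statistic is n times the R^2
#' of the auxiliary regression of the (scaled) squared residuals on x,
#' referred to a chi-square with 1 df.
#'
#' @param pairs A [paired_measurements()] object, n >= 5.
#' @param studentized Use the Koenker studentized variant (default TRUE).
#' @return A list with \code{bp_statistic}, \code{df}, \code{p_value} and
#'   \code{studentized}.
#' @export
breusch_pagan <- function(pairs, studentized = TRUE) {
  check_pairs(pairs, 5L, "the Breusch-Pagan test")
  if (stats::sd(pairs$x) == 0) stop("x is constant; cannot regress y on x")
  fit <- stats::lm(y ~ x, data = list(x = pairs$x, y = pairs$y))
  ht <- lmtest::bptest(fit, studentize = studentized)
  list(bp_statistic = unname(ht$statistic),
       df = unname(ht$parameter),
       p_value = ht$p.value,
       studentized = studentized)
}

#' Mahalanobis multivariate outlier screen
#'
#' Computes the Mahalanobis distance of each (x, y) pair from the
#' bivariate centroid and flags points beyond the square root of a
#' chi-square(2) quantile — under bivariate normality the squared distance
#' is approximately chi-square with 2 df. The classical mean/covariance
#' estimate is the default; \code{robust = TRUE} uses the MCD estimate
#' (\code{MASS::cov.rob}), which resists masking when several outliers are
#' present.
#'
#' @param pairs A [paired_measurements()] object, n >= 5.
#' @param alpha_quantile Chi-square quantile for the cutoff (default 0.975).
#' @param robust Use the minimum covariance determinant estimator.
#' @return A list with \code{distances} (length n, >= 0), \code{cutoff},
#'   \code{flags} (logical) and \code{n_flagged}.
#' @export
mahalanobis_outliers <- function(pairs, alpha_quantile = 0.975,
                                 robust = FALSE) {
  check_pairs(pairs, 5L, "Mahalanobis outlier screening")
  z <- cbind(pairs$x, pairs$y)
  if (robust) {
    est <- MASS::cov.rob(z, method = "mcd")
    center <- est$center
    covmat <- est$cov
  } else {
    center <- colMeans(z)
    covmat <- stats::cov(z)
  }
  if (!is.finite(rcond_2x2(covmat)) || rcond_2x2(covmat) < 1e-12) {
    stop("covariance of (x, y) is (near-)singular: the two methods are ",
         "collinear, Mahalanobis distances are undefined")
  }
  d2 <- stats::mahalanobis(z, center, covmat)
  cutoff <- sqrt(stats::qchisq(alpha_quantile, df = 2))
  flags <- sqrt(d2) > cutoff
  list(distances = sqrt(d2), cutoff = cutoff, flags = flags,
       n_flagged = sum(flags))
}

rcond_2x2 <- function(m) {
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (max(ev) <= 0) return(0)
  min(ev) / max(ev)
}

#' Run the full assumption-checking engine for one method pair
#'
#' Bundles the four checks that gate method selection: normality of the
#' differences, difference-vs-mean association, Breusch-Pagan
#' heteroscedasticity, and Mahalanobis outlier screening.
#'
#' @param pairs A [paired_measurements()] object, n >= 5.
#' @param alpha Significance level used throughout.
#' @param bp_studentized Studentized Breusch-Pagan (default TRUE).
#' @param outlier_quantile Chi-square quantile for the outlier cutoff.
#' @param robust_outliers Use the MCD covariance for outlier screening.
#' @param force_association_method Optional override for the association
#'   check ("pearson"/"spearman").
#' @return An object of class \code{"assumption_report"}: a list with
#'   \code{normality}, \code{diff_mean_association},
#'   \code{heteroscedasticity}, \code{outliers} and the resolved
#'   \code{options}.
#' @export
run_assumptions <- function(pairs, alpha = 0.05, bp_studentized = TRUE,
                            outlier_quantile = 0.975,
                            robust_outliers = FALSE,
                            force_association_method = NULL) {
  check_pairs(pairs, 5L, "assumption checking")
  d <- pairs$y - pairs$x
  report <- list(
    normality = check_normality(d, alpha),
    diff_mean_association = check_diff_mean_association(
      pairs, alpha, force_method = force_association_method),
    heteroscedasticity = breusch_pagan(pairs, studentized = bp_studentized),
    outliers = mahalanobis_outliers(pairs, alpha_quantile = outlier_quantile,
                                    robust = robust_outliers),
    options = list(alpha = alpha, bp_studentized = bp_studentized,
                   outlier_quantile = outlier_quantile,
                   robust_outliers = robust_outliers)
  )
  report$heteroscedastic <- report$heteroscedasticity$p_value < alpha
  report$has_outliers <- report$outliers$n_flagged > 0
  class(report) <- "assumption_report"
  report
}

#' @export
print.assumption_report <- function(x, ...) {
  a <- x$options$alpha
  cat("Assumption report (alpha =", a, ")\n")
  cat(sprintf("  normality of differences: %s, p = %.4g -> %s\n",
              x$normality$test_name, x$normality$p_value,
              if (x$normality$is_normal) "normal" else "non-normal"))
  cat(sprintf("  difference-vs-mean association: %s r = %.3f, p = %.4g -> %s\n",
              x$diff_mean_association$method,
              x$diff_mean_association$coefficient,
              x$diff_mean_association$p_value,
              if (x$diff_mean_association$is_associated) "associated"
              else "no association"))
  cat(sprintf("  Breusch-Pagan: LM = %.3f (df %d), p = %.4g -> %s\n",
              x$heteroscedasticity$bp_statistic, x$heteroscedasticity$df,
              x$heteroscedasticity$p_value,
              if (x$heteroscedastic) "heteroscedastic" else "homoscedastic"))
  cat(sprintf("  Mahalanobis outliers: %d flagged (cutoff %.3f)\n",
              x$outliers$n_flagged, x$outliers$cutoff))
  invisible(x)
}
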