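#' ANOVA mean squares for an n x k reliability layout
#'
#' Two-way decomposition of a complete subjects-by-methods matrix into
#' between-subject (MSR), between-method (MSC), residual (MSE) and
#' within-subject (MSW) mean squares — the building blocks of every ICC
#' form.
#'
#' @param m Numeric matrix, n subjects x k methods, complete.
#' @return A list with \code{msr}, \code{msc}, \code{mse}, \code{msw},
#'   \code{n}, \code{k}.
#' @export
anova_mean_squares <- function(m) {
  m <- as.matrix(m)
  if (!is.numeric(m) || anyNA(m)) stop("a complete numeric matrix is required")
  n <- nrow(m)
  k <- ncol(m)
  if (n < 2L || k < 2L) stop("need at least 2 subjects and 2 methods")
  g <- mean(m)
  rmeans <- rowMeans(m)
  cmeans <- colMeans(m)
  ssr <- k * sum((rmeans - g)^2)
  ssc <- n * sum((cmeans - g)^2)
  resid <- m - outer(rmeans, rep(1, k)) - outer(rep(1, n), cmeans) + g
  sse <- sum(resid^2)
  ssw <- sum((m - rmeans)^2)
  list(msr = ssr / (n - 1),
       msc = ssc / (k - 1),
       mse = sse / ((n - 1) * (k - 1)),
       msw = ssw / (n * (k - 1)),
       n = n, k = k)
}

#' Intraclass correlation coefficient (McGraw-Wong grid)
#'
#' Computes the ICC for any combination of model (one-way random, two-way
#' random, two-way mixed), definition (consistency vs absolute agreement)
#' and unit (single vs average measurement). Two-way random and two-way
#' mixed share point estimates and intervals; they differ only in the
#' population the result generalises to, which is recorded in the output.
#'
#' Confidence intervals use the exact F-interval construction for the
#' one-way and consistency forms and the Satterthwaite approximation for
#' absolute agreement. The significance test is F = MSR/MSE (two-way) or
#' MSR/MSW (one-way) against ICC = 0.
#'
#' @param table A [method_table()] (or complete numeric matrix), n >= 5
#'   subjects and k >= 2 methods.
#' @param model \code{"twoway_mixed"} (default: methods fixed, subjects
#'   random — the usual method-comparison design), \code{"twoway_random"}
#'   or \code{"oneway_random"}.
#' @param definition \code{"consistency"} (default) or
#'   \code{"absolute_agreement"}; ignored for the one-way model, which is
#'   inherently an absolute-agreement index.
#' @param unit \code{"single"} (default) or \code{"average"}.
#' @param level Confidence level.
#' @param scale Interpretation scale passed to [interpret_index()].
#' @return An object of class \code{"icc_result"}.
#' @examples
#' m <- cbind(a = c(1, 2, 3, 4, 5, 6), b = c(1.1, 2, 3.2, 3.9, 5.1, 5.8))
#' compute_icc(method_table(as.data.frame(m)))
#' @export
compute_icc <- function(table,
                        model = c("twoway_mixed", "twoway_random",
                                  "oneway_random"),
                        definition = c("consistency", "absolute_agreement"),
                        unit = c("single", "average"),
                        level = 0.95, scale = "koo_li") {
  model <- match.arg(model)
  definition <- match.arg(definition)
  unit <- match.arg(unit)
  m <- if (inherits(table, "method_table")) as.matrix(table$data) else
    as.matrix(table)
  if (nrow(m) < 5L) stop("ICC requires at least 5 subjects")
  ms <- anova_mean_squares(m)
  n <- ms$n; k <- ms$k
  alpha <- 1 - level
  if (ms$msr == 0) stop("zero between-subject variance: ICC is undefined")

  if (model == "oneway_random") {
    icc_s <- (ms$msr - ms$msw) / (ms$msr + (k - 1) * ms$msw)
    icc_a <- (ms$msr - ms$msw) / ms$msr
    f <- ms$msr / ms$msw
    df1 <- n - 1; df2 <- n * (k - 1)
    fl <- f / stats::qf(1 - alpha / 2, df1, df2)
    fu <- f * stats::qf(1 - alpha / 2, df2, df1)
    ci_s <- c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
    ci_a <- c(1 - 1 / fl, 1 - 1 / fu)
  } else if (definition == "consistency") {
    icc_s <- (ms$msr - ms$mse) / (ms$msr + (k - 1) * ms$mse)
    icc_a <- (ms$msr - ms$mse) / ms$msr
    f <- ms$msr / ms$mse
    df1 <- n - 1; df2 <- (n - 1) * (k - 1)
    fl <- f / stats::qf(1 - alpha / 2, df1, df2)
    fu <- f * stats::qf(1 - alpha / 2, df2, df1)
    ci_s <- c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
    ci_a <- c(1 - 1 / fl, 1 - 1 / fu)
  } else { # two-way absolute agreement
    icc_s <- (ms$msr - ms$mse) /
      (ms$msr + (k - 1) * ms$mse + k * (ms$msc - ms$mse) / n)
    icc_a <- (ms$msr - ms$mse) / (ms$msr + (ms$msc - ms$mse) / n)
    f <- ms$msr / ms$mse
    df1 <- n - 1; df2 <- (n - 1) * (k - 1)
    # Satterthwaite df for the absolute-agreement interval
    fj <- ms$msc / ms$mse
    a <- k * icc_s / (n * (1 - icc_s))
    b <- 1 + k * icc_s * (n - 1) / (n * (1 - icc_s))
    v <- (a * fj + b)^2 /
      (a^2 * fj^2 / (k - 1) + b^2 / ((n - 1) * (k - 1)))
    f1 <- stats::qf(1 - alpha / 2, n - 1, v)
    f2 <- stats::qf(1 - alpha / 2, v, n - 1)
    lo_s <- n * (ms$msr - f1 * ms$mse) /
      (f1 * (k * ms$msc + (k * n - k - n) * ms$mse) + n * ms$msr)
    hi_s <- n * (f2 * ms$msr - ms$mse) /
      (k * ms$msc + (k * n - k - n) * ms$mse + n * f2 * ms$msr)
    ci_s <- c(lo_s, hi_s)
    sb <- function(r) r * k / (1 + (k - 1) * r)   # Spearman-Brown step-up
    ci_a <- sb(ci_s)
  }

  icc <- if (unit == "single") icc_s else icc_a
  ci <- if (unit == "single") ci_s else ci_a
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  res <- list(model = model, definition = definition, unit = unit,
              icc = icc, ci = ci, f_value = f, df1 = df1, df2 = df2,
              p_value = p, mean_squares = ms, n = n, k = k, level = level,
              interpretation = interpret_index(icc, "icc", scale))
  class(res) <- "icc_result"
  res
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC (%s, %s, %s): %.4f  [%.4f, %.4f]\n",
              x$model, x$definition, x$unit, x$icc, x$ci[1], x$ci[2]))
  cat(sprintf("  F(%s, %s) = %.3f, p = %.3g -> %s agreement\n",
              format(x$df1), format(round(x$df2, 2)), x$f_value, x$p_value,
              x$interpretation))
  invisible(x)
}

#' Lin's concordance correlation coefficient
#'
#' Measures how far paired measurements fall from the 45-degree identity
#' line. Factorises exactly as CCC = rho * C_b: Pearson's rho (precision)
#' times the bias correction factor C_b (accuracy), where
#' C_b = 2 / (v + 1/v + u^2) with v the SD ratio and u the standardised
#' mean shift. Moments use the biased 1/n denominators of Lin (1989) by
#' default; \code{denominator = "n-1"} switches to sample moments (the
#' two conventions coincide as n grows). The confidence interval is the
#' inverse Fisher z interval with Lin's asymptotic variance.
#'
#' @param pairs A [paired_measurements()] object, n >= 3, both variances
#'   positive.
#' @param level Confidence level.
#' @param denominator \code{"n"} (Lin's original) or \code{"n-1"}.
#' @param scale Interpretation scale passed to [interpret_index()].
#' @return An object of class \code{"ccc_result"} with \code{ccc},
#'   \code{ci}, \code{pearson_rho}, \code{c_b}, \code{interpretation}.
#' @examples
#' pm <- paired_measurements(1:10, 1:10 + 0.5)
#' compute_ccc(pm)
#' @export
compute_ccc <- function(pairs, level = 0.95, denominator = c("n", "n-1"),
                        scale = "mcbride") {
  check_pairs(pairs, 3L, "the concordance correlation coefficient")
  denominator <- match.arg(denominator)
  x <- pairs$x; y <- pairs$y; n <- pairs$n
  div <- if (denominator == "n") n else n - 1
  mx <- mean(x); my <- mean(y)
  sx2 <- sum((x - mx)^2) / div
  sy2 <- sum((y - my)^2) / div
  sxy <- sum((x - mx) * (y - my)) / div
  if (sx2 == 0 || sy2 == 0) {
    stop("zero variance in x or y: the CCC is undefined")
  }
  ccc <- 2 * sxy / (sx2 + sy2 + (mx - my)^2)
  rho <- sxy / sqrt(sx2 * sy2)
  v <- sqrt(sx2 / sy2)
  u <- (mx - my) / (sx2 * sy2)^0.25
  c_b <- 2 / (v + 1 / v + u^2)
  # Lin's variance of the CCC, transformed to the z scale (Lin 1989 with
  # the published corrections)
  if (n > 2 && abs(ccc) < 1 && abs(rho) > 0) {
    se_ccc <- sqrt(((1 - rho^2) * ccc^2 * (1 - ccc^2) / rho^2 +
                      2 * ccc^3 * (1 - ccc) * u^2 / rho -
                      0.5 * ccc^4 * u^4 / rho^2) / (n - 2))
    z <- atanh(ccc)
    se_z <- se_ccc / (1 - ccc^2)
    zq <- stats::qnorm((1 + level) / 2)
    ci <- tanh(c(z - zq * se_z, z + zq * se_z))
  } else {
    ci <- c(NA_real_, NA_real_)
  }
  res <- list(ccc = ccc, ci = ci, pearson_rho = rho, c_b = c_b,
              n = n, level = level, denominator = denominator,
              interpretation = interpret_index(ccc, "ccc", scale))
  class(res) <- "ccc_result"
  res
}

#' @export
print.ccc_result <- function(x, ...) {
  cat(sprintf("Lin's CCC: %.4f  [%.4f, %.4f]\n", x$ccc, x$ci[1], x$ci[2]))
  cat(sprintf("  precision (Pearson rho): %.4f; accuracy (C_b): %.4f -> %s\n",
              x$pearson_rho, x$c_b, x$interpretation))
  invisible(x)
}

# Interpretation scales are data, not code: each entry is an increasing
# break vector with one more label than breaks. Values on a boundary take
# the higher label.
index_scales <- list(
  icc = list(
    koo_li = list(breaks = c(0.5, 0.75, 0.9),
                  labels = c("poor", "moderate", "good", "excellent")),
    mcs_paper = list(breaks = 0.95, labels = c("high", "excellent"))
  ),
  ccc = list(
    mcbride = list(breaks = c(0.90, 0.95, 0.99),
                   labels = c("poor", "moderate", "substantial",
                              "almost perfect")),
    mcs_paper = list(breaks = 0.95, labels = c("moderate", "high"))
  )
)

#' Map an agreement index to a verbal label
#'
#' Default scales: Koo-Li for the ICC (poor < 0.5 <= moderate < 0.75 <=
#' good < 0.9 <= excellent) and McBride for the CCC (poor < 0.90 <=
#' moderate < 0.95 <= substantial < 0.99 <= almost perfect). An
#' \code{"mcs_paper"} scale with a single 0.95 cutoff is also provided.
#' Boundary values take the higher label.
#'
#' @param value Index value in \[-1, 1\].
#' @param index_kind \code{"icc"} or \code{"ccc"}.
#' @param scale Scale name, or a list with \code{breaks} and \code{labels}.
#' @return A character label.
#' @examples
#' interpret_index(0.95, "icc")
#' interpret_index(0.942, "ccc")
#' @export
interpret_index <- function(value, index_kind = c("icc", "ccc"),
                            scale = NULL) {
  index_kind <- match.arg(index_kind)
  if (!is.finite(value) || value < -1 || value > 1) {
    stop("index value must lie in [-1, 1]")
  }
  if (is.null(scale)) {
    scale <- if (index_kind == "icc") "koo_li" else "mcbride"
  }
  if (is.character(scale)) {
    sc <- index_scales[[index_kind]][[scale]]
    if (is.null(sc)) {
      stop("unknown ", index_kind, " scale '", scale, "'; available: ",
           paste(names(index_scales[[index_kind]]), collapse = ", "))
    }
  } else {
    sc <- scale
    stopifnot(is.numeric(sc$breaks), length(sc$labels) == length(sc$breaks) + 1)
  }
  sc$labels[findInterval(value, sc$breaks) + 1L]
}
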