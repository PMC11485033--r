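#' Bland-Altman analysis of absolute agreement
#'
#' Computes the bias (mean of the differences d = y - x), its standard
#' deviation, the limits of agreement (LoA) and confidence intervals for
#' all three lines. LoA are the classical bias +/- 1.96 SD (normal
#' quantile at \code{level}); the CI of the bias uses Student t with
#' n - 1 df, and each LoA CI uses the classical approximation
#' Var(LoA) ~ 3 SD^2 / n, again with t(n-1). Setting
#' \code{loa_quantile = "t"} replaces the 1.96 in the LoA themselves with
#' the t(n-1) quantile.
#'
#' @param pairs A [paired_measurements()] object, n >= 3.
#' @param level Confidence / agreement level (default 0.95).
#' @param loa_quantile \code{"normal"} (default, z = 1.959964 at 0.95) or
#'   \code{"t"}.
#' @return An object of class \code{"bland_altman"} with \code{n},
#'   \code{mean_diff}, \code{sd_diff}, \code{loa_lower}, \code{loa_upper},
#'   \code{ci_mean}, \code{ci_loa_lower}, \code{ci_loa_upper},
#'   \code{level}, \code{degenerate} and \code{unit_label}.
#' @examples
#' pm <- paired_measurements(c(10, 11, 12, 13, 14), c(8, 10, 12, 14, 16))
#' compute_bland_altman(pm)
#' @export
compute_bland_altman <- function(pairs, level = 0.95,
                                 loa_quantile = c("normal", "t")) {
  check_pairs(pairs, 3L, "Bland-Altman analysis")
  loa_quantile <- match.arg(loa_quantile)
  stopifnot(level > 0, level < 1)
  d <- pairs$y - pairs$x
  n <- pairs$n
  mean_diff <- mean(d)
  sd_diff <- stats::sd(d)
  if (sd_diff == 0) {
    warning("all differences are identical: zero-width limits of ",
            "agreement, no confidence intervals")
    res <- list(n = n, mean_diff = mean_diff, sd_diff = 0,
                loa_lower = mean_diff, loa_upper = mean_diff,
                ci_mean = c(NA_real_, NA_real_),
                ci_loa_lower = c(NA_real_, NA_real_),
                ci_loa_upper = c(NA_real_, NA_real_),
                level = level, loa_quantile = loa_quantile,
                degenerate = TRUE, unit_label = pairs$unit_label)
    class(res) <- "bland_altman"
    return(res)
  }
  q <- if (loa_quantile == "normal") {
    stats::qnorm((1 + level) / 2)
  } else {
    stats::qt((1 + level) / 2, df = n - 1)
  }
  tq <- stats::qt((1 + level) / 2, df = n - 1)
  loa_lower <- mean_diff - q * sd_diff
  loa_upper <- mean_diff + q * sd_diff
  se_mean <- sd_diff / sqrt(n)
  se_loa <- sqrt(3 * sd_diff^2 / n)
  res <- list(
    n = n, mean_diff = mean_diff, sd_diff = sd_diff,
    loa_lower = loa_lower, loa_upper = loa_upper,
    ci_mean = c(mean_diff - tq * se_mean, mean_diff + tq * se_mean),
    ci_loa_lower = c(loa_lower - tq * se_loa, loa_lower + tq * se_loa),
    ci_loa_upper = c(loa_upper - tq * se_loa, loa_upper + tq * se_loa),
    level = level, loa_quantile = loa_quantile,
    degenerate = FALSE, unit_label = pairs$unit_label
  )
  class(res) <- "bland_altman"
  res
}

#' Rebuild a Bland-Altman result from published summary numbers
#'
#' Reconstructs the full result (SD of differences and all confidence
#' intervals) from the three numbers a typical publication prints — the
#' mean difference, the two limits of agreement — plus the sample size.
#' The SD is recovered as the LoA width divided by twice the agreement
#' quantile. Useful for internal-consistency checks of published
#' agreement tables.
#'
#' @param mean_diff Printed mean difference.
#' @param loa_lower,loa_upper Printed limits of agreement.
#' @param n Sample size.
#' @param level Agreement/confidence level (default 0.95).
#' @return A \code{"bland_altman"} object; \code{mean_diff} is taken from
#'   the input, not re-derived from the LoA midpoint, so that
#'   \code{(loa_lower + loa_upper) / 2 - mean_diff} can serve as a
#'   consistency diagnostic (stored as \code{midpoint_discrepancy}).
#' @export
bland_altman_from_summary <- function(mean_diff, loa_lower, loa_upper, n,
                                      level = 0.95) {
  stopifnot(loa_upper >= loa_lower, n >= 3)
  z <- stats::qnorm((1 + level) / 2)
  tq <- stats::qt((1 + level) / 2, df = n - 1)
  sd_diff <- (loa_upper - loa_lower) / (2 * z)
  se_mean <- sd_diff / sqrt(n)
  se_loa <- sqrt(3 * sd_diff^2 / n)
  res <- list(
    n = n, mean_diff = mean_diff, sd_diff = sd_diff,
    loa_lower = loa_lower, loa_upper = loa_upper,
    ci_mean = c(mean_diff - tq * se_mean, mean_diff + tq * se_mean),
    ci_loa_lower = c(loa_lower - tq * se_loa, loa_lower + tq * se_loa),
    ci_loa_upper = c(loa_upper - tq * se_loa, loa_upper + tq * se_loa),
    level = level, loa_quantile = "normal", degenerate = sd_diff == 0,
    unit_label = "",
    midpoint_discrepancy = (loa_lower + loa_upper) / 2 - mean_diff
  )
  class(res) <- "bland_altman"
  res
}

#' Scatter and reference-line data for a Bland-Altman plot
#'
#' @param result A \code{"bland_altman"} object computed from \code{pairs}.
#' @param pairs The [paired_measurements()] the result was computed from.
#' @return A list with \code{points} (data.frame of \code{mean} and
#'   \code{diff}), \code{lines} (named vector: \code{mean},
#'   \code{loa_lower}, \code{loa_upper}) and \code{ci_bands} (data.frame
#'   with one row per line, or NULL when the result is degenerate).
#' @export
bland_altman_plot_data <- function(result, pairs) {
  stopifnot(inherits(result, "bland_altman"))
  check_pairs(pairs, 1L, "plotting")
  if (pairs$n != result$n) {
    stop("pairs (n = ", pairs$n, ") do not match the result (n = ",
         result$n, ")")
  }
  pts <- data.frame(mean = (pairs$x + pairs$y) / 2, diff = pairs$y - pairs$x)
  lines <- c(mean = result$mean_diff,
             loa_lower = result$loa_lower,
             loa_upper = result$loa_upper)
  bands <- if (result$degenerate) NULL else data.frame(
    line = c("mean", "loa_lower", "loa_upper"),
    lo = c(result$ci_mean[1], result$ci_loa_lower[1], result$ci_loa_upper[1]),
    hi = c(result$ci_mean[2], result$ci_loa_lower[2], result$ci_loa_upper[2])
  )
  list(points = pts, lines = lines, ci_bands = bands)
}

#' Plot method for Bland-Altman results
#'
#' Draws the difference-vs-mean scatter with the bias line (solid) and
#' limits of agreement (dashed); CI bands are shaded when available.
#'
#' @param x A \code{"bland_altman"} object.
#' @param pairs The [paired_measurements()] used to compute it.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.bland_altman <- function(x, pairs, ...) {
  pd <- bland_altman_plot_data(x, pairs)
  ylim <- range(pd$points$diff, pd$lines,
                if (!is.null(pd$ci_bands)) c(pd$ci_bands$lo, pd$ci_bands$hi))
  graphics::plot(pd$points$mean, pd$points$diff,
                 xlab = "Mean of methods", ylab = "Difference (test - reference)",
                 ylim = ylim, pch = 19, col = "grey30", ...)
  if (!is.null(pd$ci_bands)) {
    usr <- graphics::par("usr")
    for (i in seq_len(nrow(pd$ci_bands))) {
      graphics::rect(usr[1], pd$ci_bands$lo[i], usr[2], pd$ci_bands$hi[i],
                     col = grDevices::adjustcolor("steelblue", 0.15),
                     border = NA)
    }
  }
  graphics::abline(h = pd$lines["mean"], lwd = 2)
  graphics::abline(h = pd$lines[c("loa_lower", "loa_upper")], lty = 2)
  invisible(pd)
}

#' Plain-language interpretation of a Bland-Altman result
#'
#' Renders the standard clinical sentence: how far above and below the
#' reference the test method may read, based on the limits of agreement,
#' and (optionally) whether the limits fall within a clinically acceptable
#' difference.
#'
#' @param result A \code{"bland_altman"} object.
#' @param clinical_limit Optional symmetric clinical acceptability limit
#'   in measurement units.
#' @param unit_label Unit label; defaults to the one stored in the result.
#' @return A character string.
#' @export
interpret_bland_altman <- function(result, clinical_limit = NULL,
                                   unit_label = NULL) {
  stopifnot(inherits(result, "bland_altman"))
  u <- if (is.null(unit_label)) result$unit_label else unit_label
  usp <- if (nzchar(u)) paste0(" ", u) else ""
  if (result$degenerate) {
    txt <- sprintf(
      "The two methods differ by a constant %.2f%s for every subject.",
      result$mean_diff, usp)
  } else if (result$mean_diff < 0) {
    # test reads lower on average: it may read |loa_lower| above and
    # loa_upper below the reference
    txt <- sprintf(
      paste0("The test method may read up to %.2f%s more and %.2f%s less ",
             "than the reference method (mean difference %.2f%s)."),
      abs(result$loa_lower), usp, result$loa_upper, usp,
      result$mean_diff, usp)
  } else {
    txt <- sprintf(
      paste0("The test method may read up to %.2f%s less and %.2f%s more ",
             "than the reference method (mean difference %.2f%s)."),
      abs(result$loa_lower), usp, result$loa_upper, usp,
      result$mean_diff, usp)
  }
  if (!is.null(clinical_limit)) {
    inside <- result$loa_lower >= -abs(clinical_limit) &&
      result$loa_upper <= abs(clinical_limit)
    txt <- paste(txt, if (inside) {
      sprintf("The limits of agreement fall within the clinical limit of %.2f%s.",
              abs(clinical_limit), usp)
    } else {
      sprintf("The limits of agreement exceed the clinical limit of %.2f%s.",
              abs(clinical_limit), usp)
    })
  }
  txt
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman analysis (n = %d, level = %.2f)\n", x$n, x$level))
  cat(sprintf("  mean difference: %.4f  [%.4f, %.4f]\n",
              x$mean_diff, x$ci_mean[1], x$ci_mean[2]))
  cat(sprintf("  SD of differences: %.4f\n", x$sd_diff))
  cat(sprintf("  lower LoA: %.4f  [%.4f, %.4f]\n",
              x$loa_lower, x$ci_loa_lower[1], x$ci_loa_lower[2]))
  cat(sprintf("  upper LoA: %.4f  [%.4f, %.4f]\n",
              x$loa_upper, x$ci_loa_upper[1], x$ci_loa_upper[2]))
  invisible(x)
}
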