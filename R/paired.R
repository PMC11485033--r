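#' Paired measurements from two methods
#'
#' Container for one method pair: a reference method \code{x} and a test
#' method \code{y} measured on the same subjects in the same physical units.
#' Every agreement statistic and regression estimator in the package takes
#' one of these as input.
#'
#' @param x Numeric vector, reference method.
#' @param y Numeric vector, test method; same length and units as \code{x}.
#' @param unit_label Free-text unit label (e.g. \code{"g"}); used in
#'   interpretation text only.
#'
#' @return An object of class \code{"paired_measurements"}: a list with
#'   elements \code{x}, \code{y}, \code{n} and \code{unit_label}.
#' @examples
#' pm <- paired_measurements(c(3000, 3200, 2800), c(2950, 3180, 2760), "g")
#' pm$n
#' @export
paired_measurements <- function(x, y, unit_label = "") {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y)) {
    stop("x and y must have the same length (one row per subject)")
  }
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("paired measurements must be finite; drop incomplete rows first")
  }
  if (length(x) < 1L) stop("at least one pair is required")
  structure(
    list(x = x, y = y, n = length(x),
         unit_label = as.character(unit_label)[1L]),
    class = "paired_measurements"
  )
}

#' @export
print.paired_measurements <- function(x, ...) {
  cat("Paired measurements: n =", x$n,
      if (nzchar(x$unit_label)) paste0("[", x$unit_label, "]") else "", "\n")
  cat("  reference (x): ", summary_line(x$x), "\n")
  cat("  test      (y): ", summary_line(x$y), "\n")
  invisible(x)
}

summary_line <- function(v) {
  sprintf("mean %.4g, sd %.4g, range [%.4g, %.4g]",
          mean(v), stats::sd(v), min(v), max(v))
}

# Guard used by the inferential operations: they need a minimum n and
# non-degenerate variation.
check_pairs <- function(pairs, min_n = 3L, what = "this analysis") {
  if (!inherits(pairs, "paired_measurements")) {
    stop("expected a 'paired_measurements' object; see paired_measurements()")
  }
  if (pairs$n < min_n) {
    stop(sprintf("%s requires at least %d pairs (got %d)",
                 what, min_n, pairs$n))
  }
  invisible(pairs)
}
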