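#' Write an analysis report to disk
#'
#' \code{"json"} serialises the full report (all nesting, full numeric
#' precision) and is the lossless round-trip format. \code{"csv"} writes
#' one file per analysis section (\code{<path>_assumptions.csv},
#' \code{<path>_bland_altman.csv}, \code{<path>_indices.csv},
#' \code{<path>_regression.csv}) with numerics at full double precision.
#' XLSX export is not available in this build (no xlsx writer is
#' installed); requesting it raises an informative error.
#'
#' @param report An \code{"mc_report"} from [run_comparison()].
#' @param path Output path (for csv, used as a prefix; any \code{.csv}
#'   extension is stripped).
#' @param format \code{"json"} (default), \code{"csv"} or \code{"xlsx"}.
#' @return Invisibly, the vector of files written.
#' @export
write_report <- function(report, path, format = c("json", "csv", "xlsx")) {
  stopifnot(inherits(report, "mc_report"))
  format <- match.arg(format)
  has_content <- !is.null(report$icc) ||
    any(vapply(report$comparisons, function(cmp) {
      !is.null(cmp$assumptions) || !is.null(cmp$bland_altman) ||
        !is.null(cmp$ccc) || !is.null(cmp$regression)
    }, logical(1)))
  if (!has_content) stop("the report contains no analyses; nothing to write")
  if (format == "json") {
    # 17 significant digits: doubles survive the round-trip bit-exactly
    jsonlite::write_json(strip_classes(report), path, auto_unbox = TRUE,
                         digits = I(17), null = "null", force = TRUE)
    return(invisible(path))
  }
  if (format == "xlsx") {
    stop("xlsx export is not available (no xlsx writer installed); ",
         "use format = 'json' or 'csv'")
  }
  prefix <- sub("\\.csv$", "", path)
  sections <- report_sections(report)
  written <- character(0)
  for (nm in names(sections)) {
    if (is.null(sections[[nm]]) || nrow(sections[[nm]]) == 0) next
    f <- paste0(prefix, "_", nm, ".csv")
    df <- sections[[nm]]
    # format doubles at 17 significant digits so csv round-trips
    for (j in seq_along(df)) {
      if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
    }
    utils::write.csv(df, f, row.names = FALSE)
    written <- c(written, f)
  }
  invisible(written)
}

strip_classes <- function(x) {
  if (is.list(x)) {
    x <- unclass(x)
    lapply(x, strip_classes)
  } else {
    x
  }
}

#' Read back a JSON report
#'
#' @param path Path to a JSON file written by [write_report()].
#' @return The report as a plain nested list (classes are not restored).
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

# Flat per-section data frames (the csv/xlsx sheet shapes)
report_sections <- function(report) {
  comps <- report$comparisons
  grab <- function(f) do.call(rbind, lapply(comps, f))
  assumptions <- grab(function(cmp) {
    a <- cmp$assumptions
    if (is.null(a)) return(NULL)
    data.frame(test = cmp$test,
               normality_test = a$normality$test_name,
               normality_statistic = a$normality$statistic,
               normality_p = a$normality$p_value,
               association_method = a$diff_mean_association$method,
               association_coefficient = a$diff_mean_association$coefficient,
               association_p = a$diff_mean_association$p_value,
               bp_statistic = a$heteroscedasticity$bp_statistic,
               bp_df = a$heteroscedasticity$df,
               bp_p = a$heteroscedasticity$p_value,
               outlier_cutoff = a$outliers$cutoff,
               n_outliers = a$outliers$n_flagged)
  })
  bland_altman <- grab(function(cmp) {
    b <- cmp$bland_altman
    if (is.null(b)) return(NULL)
    data.frame(test = cmp$test, n = b$n, mean_diff = b$mean_diff,
               sd_diff = b$sd_diff,
               mean_ci_lo = b$ci_mean[1], mean_ci_hi = b$ci_mean[2],
               loa_lower = b$loa_lower,
               loa_lower_ci_lo = b$ci_loa_lower[1],
               loa_lower_ci_hi = b$ci_loa_lower[2],
               loa_upper = b$loa_upper,
               loa_upper_ci_lo = b$ci_loa_upper[1],
               loa_upper_ci_hi = b$ci_loa_upper[2])
  })
  indices <- grab(function(cmp) {
    cc <- cmp$ccc
    if (is.null(cc)) return(NULL)
    data.frame(test = cmp$test, index = "ccc", value = cc$ccc,
               ci_lo = cc$ci[1], ci_hi = cc$ci[2],
               pearson_rho = cc$pearson_rho, c_b = cc$c_b,
               interpretation = cc$interpretation)
  })
  if (!is.null(report$icc)) {
    ic <- report$icc
    indices <- rbind(
      data.frame(test = "all_methods", index = "icc", value = ic$icc,
                 ci_lo = ic$ci[1], ci_hi = ic$ci[2],
                 pearson_rho = NA_real_, c_b = NA_real_,
                 interpretation = ic$interpretation),
      indices)
  }
  regression <- grab(function(cmp) {
    r <- cmp$regression
    if (is.null(r)) return(NULL)
    do.call(rbind, lapply(names(r$fits), function(m) {
      f <- r$fits[[m]]
      b <- r$bias[[m]]
      data.frame(test = cmp$test, method = m,
                 intercept = f$intercept,
                 intercept_ci_lo = f$intercept_ci[1],
                 intercept_ci_hi = f$intercept_ci[2],
                 slope = f$slope,
                 slope_ci_lo = f$slope_ci[1], slope_ci_hi = f$slope_ci[2],
                 systematic_bias = b$systematic_bias,
                 proportional_bias = b$proportional_bias)
    }))
  })
  list(assumptions = assumptions, bland_altman = bland_altman,
       indices = indices, regression = regression)
}

#' Published cohort summaries for the Hadlock worked example
#'
#' Summary statistics from a published clinical comparison of the five
#' Hadlock estimated-fetal-weight formulas against birth weight in 975
#' term singleton pregnancies: the Bland-Altman table (mean difference,
#' limits of agreement, all 95\% CIs), the agreement indices (ICC with
#' F test, CCC with precision/accuracy decomposition) and the
#' Passing-Bablok / Theil-Sen regression coefficients. The raw cohort is
#' not publicly deposited; these printed summaries serve as reference
#' inputs for internal-consistency checks (e.g. with
#' [bland_altman_from_summary()]).
#'
#' @param table One of \code{"bland_altman"}, \code{"indices"},
#'   \code{"regression"}.
#' @return A data.frame.
#' @examples
#' hadlock_cohort_summary("bland_altman")
#' @export
hadlock_cohort_summary <- function(table = c("bland_altman", "indices",
                                             "regression")) {
  table <- match.arg(table)
  f <- system.file("extdata", paste0("hadlock_cohort_", table, ".csv"),
                   package = "methodcompare", mustWork = TRUE)
  utils::read.csv(f, stringsAsFactors = FALSE)
}
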