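#' Configuration for a full method-comparison run
#'
#' @param input Optional path to a CSV/TSV/XLSX file (read with
#'   [read_method_table()]); alternatively supply \code{table} directly.
#' @param table Optional [method_table()] (used when \code{input} is NULL).
#' @param reference Name of the reference method column.
#' @param tests Character vector of test method columns (each compared
#'   against the reference).
#' @param analyses Subset of \code{c("assumptions", "ba", "icc", "ccc",
#'   "regression")}; default all.
#' @param level Confidence level for every interval.
#' @param alpha Significance level for every assumption check.
#' @param lambda Deming error variance ratio.
#' @param forced_methods Optional character vector of regression methods
#'   to fit regardless of the assumption-driven recommendation.
#' @param large_threshold Subject count above which pb_large replaces the
#'   exact Passing-Bablok.
#' @param clinical_limit Optional clinical acceptability limit for the
#'   Bland-Altman interpretation.
#' @param unit_label Measurement unit label for interpretation text.
#' @param seed Integer seed (drives pb_large subsampling and is recorded
#'   in the provenance).
#' @param strict If TRUE, failed Bland-Altman assumptions block the
#'   Bland-Altman section with an error; default annotates with caveats.
#' @param timestamp Record the wall-clock time in the provenance
#'   (default FALSE so that identical runs produce byte-identical
#'   reports).
#' @return A list of class \code{"run_config"}.
#' @export
run_config <- function(input = NULL, table = NULL, reference, tests,
                       analyses = c("assumptions", "ba", "icc", "ccc",
                                    "regression"),
                       level = 0.95, alpha = 0.05, lambda = 1,
                       forced_methods = NULL, large_threshold = 5000,
                       clinical_limit = NULL, unit_label = "",
                       seed = 1L, strict = FALSE, timestamp = FALSE) {
  analyses <- match.arg(analyses, several.ok = TRUE)
  if (length(analyses) == 0L) stop("at least one analysis is required")
  if (reference %in% tests) {
    stop("the reference column must not appear among the test columns")
  }
  if (length(tests) < 1L) stop("at least one test column is required")
  structure(
    list(input = input, table = table, reference = reference,
         tests = tests, analyses = analyses, level = level, alpha = alpha,
         lambda = lambda, forced_methods = forced_methods,
         large_threshold = large_threshold,
         clinical_limit = clinical_limit, unit_label = unit_label,
         seed = as.integer(seed), strict = strict, timestamp = timestamp),
    class = "run_config"
  )
}

#' Run the full method-comparison workflow
#'
#' For every test column versus the reference: assumption checks,
#' Bland-Altman analysis (annotated with caveats when the normality or
#' association assumption fails, or blocked under \code{strict}), Lin's
#' CCC, assumption-driven regression selection, the selected (or forced)
#' regression fits and their bias assessment. The ICC is computed once
#' over the full table (reference plus all test columns). The run is
#' fully deterministic given the input, configuration and seed.
#'
#' @param config A [run_config()].
#' @return An object of class \code{"mc_report"}.
#' @examples
#' tab <- method_table(data.frame(ref = c(1, 2, 3, 4, 5, 6, 7, 8),
#'                                new = c(1.1, 2.1, 2.9, 4.2, 5.1, 5.9, 7, 8.1)))
#' rep <- run_comparison(run_config(table = tab, reference = "ref",
#'                                  tests = "new", analyses = c("ba", "ccc")))
#' @export
run_comparison <- function(config) {
  stopifnot(inherits(config, "run_config"))
  tab <- if (!is.null(config$input)) {
    read_method_table(config$input)
  } else if (!is.null(config$table)) {
    config$table
  } else {
    stop("run_config needs either an input path or a method_table")
  }
  for (col in c(config$reference, config$tests)) {
    if (!col %in% tab$methods) {
      stop("column '", col, "' not found in the table (available: ",
           paste(tab$methods, collapse = ", "), ")")
    }
  }

  report <- list(
    provenance = list(
      package = "methodcompare",
      version = as.character(utils::packageVersion("methodcompare")),
      input = if (is.null(config$input)) "in-memory table" else config$input,
      n = tab$n, n_dropped = tab$n_dropped,
      reference = config$reference, tests = config$tests,
      options = config[c("analyses", "level", "alpha", "lambda",
                         "forced_methods", "large_threshold",
                         "clinical_limit", "strict")],
      seed = config$seed,
      created = if (config$timestamp) format(Sys.time(), tz = "UTC") else NULL
    ),
    icc = NULL,
    comparisons = list()
  )

  if ("icc" %in% config$analyses) {
    icc_tab <- method_table(tab$data[, c(config$reference, config$tests),
                                     drop = FALSE])
    report$icc <- compute_icc(icc_tab, level = config$level)
  }

  for (test in config$tests) {
    pairs <- method_pair(tab, config$reference, test,
                         unit_label = config$unit_label)
    cmp <- list(test = test, caveats = character(0))
    assume <- NULL
    if (any(c("assumptions", "ba", "regression") %in% config$analyses)) {
      assume <- run_assumptions(pairs, alpha = config$alpha)
      if ("assumptions" %in% config$analyses) cmp$assumptions <- assume
    }
    if ("ba" %in% config$analyses) {
      if (!is.null(assume)) {
        if (!assume$normality$is_normal) {
          cmp$caveats <- c(cmp$caveats, paste0(
            "differences are not normally distributed (p = ",
            signif(assume$normality$p_value, 3),
            "); Bland-Altman limits may be miscalibrated"))
        }
        if (assume$diff_mean_association$is_associated) {
          cmp$caveats <- c(cmp$caveats, paste0(
            "differences are associated with the measurement level (",
            assume$diff_mean_association$method, " p = ",
            signif(assume$diff_mean_association$p_value, 3),
            "); a single bias does not describe agreement across the range"))
        }
        if (config$strict && length(cmp$caveats) > 0) {
          stop("Bland-Altman assumptions failed for '", test, "': ",
               paste(cmp$caveats, collapse = "; "))
        }
      }
      cmp$bland_altman <- compute_bland_altman(pairs, level = config$level)
      cmp$ba_interpretation <- interpret_bland_altman(
        cmp$bland_altman, clinical_limit = config$clinical_limit)
    }
    if ("ccc" %in% config$analyses) {
      cmp$ccc <- compute_ccc(pairs, level = config$level)
    }
    if ("regression" %in% config$analyses) {
      if (is.null(config$forced_methods)) {
        sel <- select_method(assume, n = pairs$n,
                             large_threshold = config$large_threshold)
      } else {
        sel <- list(methods = config$forced_methods,
                    rationale = stats::setNames(
                      rep("requested explicitly", length(config$forced_methods)),
                      config$forced_methods))
      }
      fits <- lapply(sel$methods, function(m) {
        fit_method(pairs, m, level = config$level, lambda = config$lambda,
                   seed = config$seed)
      })
      names(fits) <- sel$methods
      cmp$regression <- list(
        selection = sel,
        fits = fits,
        bias = lapply(fits, assess_bias)
      )
    }
    report$comparisons[[test]] <- cmp
  }
  class(report) <- "mc_report"
  report
}

#' Render the interpretation text block for a report
#'
#' Deterministic template rendering of every interpretation the report
#' carries: the Bland-Altman sentence, the ICC and CCC labels, the bias
#' narrative for each regression fit, and any assumption caveats.
#' Sections absent from the report are simply omitted.
#'
#' @param report An \code{"mc_report"} from [run_comparison()].
#' @return A single character string (lines joined with newlines).
#' @export
render_interpretations <- function(report) {
  stopifnot(inherits(report, "mc_report"))
  out <- character(0)
  if (!is.null(report$icc)) {
    out <- c(out, sprintf(
      "ICC (%s, %s, %s) across all %d methods: %.3f [%.3f, %.3f] - %s agreement.",
      report$icc$model, report$icc$definition, report$icc$unit,
      report$icc$k, report$icc$icc, report$icc$ci[1], report$icc$ci[2],
      report$icc$interpretation))
  }
  for (cmp in report$comparisons) {
    out <- c(out, paste0("== ", report$provenance$reference, " vs ",
                         cmp$test, " =="))
    for (cv in cmp$caveats) out <- c(out, paste0("caveat: ", cv))
    if (!is.null(cmp$ba_interpretation)) out <- c(out, cmp$ba_interpretation)
    if (!is.null(cmp$ccc)) {
      out <- c(out, sprintf(
        "CCC %.3f [%.3f, %.3f] (precision %.3f, accuracy %.3f) - %s agreement.",
        cmp$ccc$ccc, cmp$ccc$ci[1], cmp$ccc$ci[2], cmp$ccc$pearson_rho,
        cmp$ccc$c_b, cmp$ccc$interpretation))
    }
    if (!is.null(cmp$regression)) {
      for (m in names(cmp$regression$fits)) {
        out <- c(out, sprintf("%s: %s", m, cmp$regression$bias[[m]]$narrative))
      }
    }
  }
  paste(out, collapse = "\n")
}

#' @export
print.mc_report <- function(x, ...) {
  cat("Method comparison report (", x$provenance$reference, " vs ",
      paste(x$provenance$tests, collapse = ", "), "; n = ",
      x$provenance$n, ")\n\n", sep = "")
  cat(render_interpretations(x), "\n")
  invisible(x)
}
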