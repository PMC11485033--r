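make_demo_report <- function(analyses = c("assumptions", "ba", "icc", "ccc",
                                          "regression")) {
  tab <- efw_table(generate_biometry(60, seed = 3))
  # treat hadlock1 EFW as the reference and hadlock4 as the test method
  run_comparison(run_config(table = tab, reference = "hadlock1",
                            tests = "hadlock4", analyses = analyses,
                            unit_label = "g", seed = 1))
}

test_that("run_comparison produces a complete deterministic report", {
  rep <- make_demo_report()
  expect_s3_class(rep, "mc_report")
  cmp <- rep$comparisons$hadlock4
  expect_s3_class(cmp$assumptions, "assumption_report")
  expect_s3_class(cmp$bland_altman, "bland_altman")
  expect_s3_class(cmp$ccc, "ccc_result")
  expect_s3_class(rep$icc, "icc_result")
  expect_true(length(cmp$regression$fits) >= 1)
  expect_equal(names(cmp$regression$fits),
               cmp$regression$selection$methods)
  # recommendation mirrors the assumption report
  expect_equal(cmp$regression$selection$methods,
               select_method(cmp$assumptions, 60)$methods)
  # unknown column fails before any computation
  tab <- efw_table(generate_biometry(10, seed = 3))
  expect_error(run_comparison(run_config(table = tab, reference = "zz",
                                         tests = "hadlock4")), "not found")
  expect_error(run_config(table = tab, reference = "a", tests = "a"),
               "must not appear")
})

test_that("a clean linear fixture recommends ols and deming without caveats", {
  g <- generate_paired(synthetic_spec(
    80, intercept = 2, slope = 1,
    noise_y = list(model = "constant_sd", magnitude = 2),
    distribution = "uniform", dist_params = c(50, 150), seed = 101))
  tab <- method_table(data.frame(ref = g$pairs$x, new = g$pairs$y))
  rep <- run_comparison(run_config(table = tab, reference = "ref",
                                   tests = "new", seed = 1))
  cmp <- rep$comparisons$new
  if (!cmp$assumptions$heteroscedastic && !cmp$assumptions$has_outliers) {
    expect_equal(cmp$regression$selection$methods, c("ols", "deming"))
  }
  expect_s3_class(cmp$bland_altman, "bland_altman")
})

test_that("heteroscedastic contaminated data route to the rank estimators", {
  g <- generate_paired(synthetic_spec(
    150, intercept = 0, slope = 1,
    noise_y = list(model = "proportional_cv", magnitude = 0.10),
    outlier_fraction = 0.05, outlier_shift = 6,
    distribution = "uniform", dist_params = c(20, 200), seed = 31))
  tab <- method_table(data.frame(ref = g$pairs$x, new = g$pairs$y))
  rep <- run_comparison(run_config(table = tab, reference = "ref",
                                   tests = "new", seed = 1))
  sel <- rep$comparisons$new$regression$selection$methods
  expect_equal(sel, c("passing_bablok", "theil_sen"))
  txt <- render_interpretations(rep)
  expect_match(txt, "passing_bablok")
  expect_match(txt, "CCC")
})

test_that("strict mode blocks on failed assumptions; default annotates caveats", {
  g <- generate_paired(synthetic_spec(
    200, intercept = 0, slope = 1,
    noise_y = list(model = "proportional_cv", magnitude = 0.15),
    distribution = "uniform", dist_params = c(10, 300), seed = 41))
  tab <- method_table(data.frame(ref = g$pairs$x, new = g$pairs$y))
  rep <- run_comparison(run_config(table = tab, reference = "ref",
                                   tests = "new", analyses = c("assumptions", "ba"),
                                   seed = 1))
  expect_gt(length(rep$comparisons$new$caveats), 0)
  expect_error(
    run_comparison(run_config(table = tab, reference = "ref", tests = "new",
                              analyses = c("assumptions", "ba"),
                              seed = 1, strict = TRUE)),
    "assumptions failed")
})

test_that("reports round-trip losslessly through json", {
  rep <- make_demo_report()
  f <- tempfile(fileext = ".json")
  write_report(rep, f, "json")
  back <- read_report(f)
  cmp <- rep$comparisons$hadlock4
  expect_identical(back$comparisons$hadlock4$bland_altman$mean_diff,
                   cmp$bland_altman$mean_diff)
  expect_identical(back$comparisons$hadlock4$bland_altman$loa_upper,
                   cmp$bland_altman$loa_upper)
  expect_identical(back$icc$icc, rep$icc$icc)
  expect_identical(back$comparisons$hadlock4$ccc$ccc, cmp$ccc$ccc)
  fitnames <- names(cmp$regression$fits)
  expect_identical(back$comparisons$hadlock4$regression$fits[[fitnames[1]]]$slope,
                   cmp$regression$fits[[1]]$slope)
})

test_that("identical config and seed give byte-identical json reports", {
  f1 <- tempfile(fileext = ".json"); f2 <- tempfile(fileext = ".json")
  write_report(make_demo_report(), f1, "json")
  write_report(make_demo_report(), f2, "json")
  expect_identical(readLines(f1), readLines(f2))
})

test_that("csv export writes one file per section at >= 12 significant digits", {
  rep <- make_demo_report()
  prefix <- tempfile()
  files <- write_report(rep, prefix, "csv")
  expect_setequal(basename(files),
                  paste0(basename(prefix), "_",
                         c("assumptions", "bland_altman", "indices",
                           "regression"), ".csv"))
  ba <- read.csv(paste0(prefix, "_bland_altman.csv"))
  expect_equal(ba$mean_diff, rep$comparisons$hadlock4$bland_altman$mean_diff,
               tolerance = 1e-12)
  reg <- read.csv(paste0(prefix, "_regression.csv"))
  expect_equal(nrow(reg),
               length(rep$comparisons$hadlock4$regression$fits))
})

test_that("xlsx export and empty reports fail loudly", {
  rep <- make_demo_report()
  expect_error(write_report(rep, tempfile(), "xlsx"), "not available")
  empty <- rep
  empty$icc <- NULL
  empty$comparisons <- list(list(test = "x", caveats = character(0)))
  class(empty) <- "mc_report"
  expect_error(write_report(empty, tempfile(), "json"), "no analyses")
})

test_that("interpretation text omits missing sections without error", {
  rep <- make_demo_report(analyses = c("ba", "ccc"))
  txt <- render_interpretations(rep)
  expect_false(grepl("passing_bablok|theil_sen|ols", txt))
  expect_match(txt, "more and")
  expect_match(txt, "CCC")
})

test_that("the bundled cohort summaries load with the published shape", {
  ba <- hadlock_cohort_summary("bland_altman")
  expect_equal(nrow(ba), 5)
  expect_equal(ba$n, rep(975, 5))
  expect_true(all(ba$loa_lower < ba$mean_diff & ba$mean_diff < ba$loa_upper))
  idx <- hadlock_cohort_summary("indices")
  expect_equal(idx$icc_df1, rep(974, 5))
  reg <- hadlock_cohort_summary("regression")
  expect_equal(nrow(reg), 10)
  expect_setequal(unique(reg$method), c("passing_bablok", "theil_sen"))
})

test_that("the command-line entry point runs end to end", {
  cli <- system.file("cli", "mcs", package = "methodcompare")
  expect_true(nzchar(cli))
  csv <- tempfile(fileext = ".csv")
  tab <- efw_table(generate_biometry(40, seed = 9))
  write.csv(tab$data, csv, row.names = FALSE)
  out <- tempfile(fileext = ".json")
  status <- system2("Rscript", c(cli, "run", "--in", csv,
                                 "--reference", "hadlock1",
                                 "--tests", "hadlock4",
                                 "--out", out, "--seed", "1"),
                    stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(out))
  back <- read_report(out)
  expect_true(is.numeric(back$comparisons$hadlock4$bland_altman$mean_diff))
})
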