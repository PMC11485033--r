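test_that("ols and wols behave on exact and weighted cases", {
  x <- c(1, 2, 3, 4, 5)
  pm <- paired_measurements(x, 2 * x + 1)
  fit <- fit_ols(pm)
  expect_equal(fit$slope, 2, tolerance = 1e-12)
  expect_equal(fit$intercept, 1, tolerance = 1e-12)
  expect_lt(fit$diagnostics$sigma, 1e-10)
  # equal user weights reproduce the unweighted fit
  pm2 <- make_line_pairs(30, a = 2, b = 1.1, sd = 3, seed = 4)
  f_un <- fit_ols(pm2)
  f_eq <- fit_ols(pm2, weights = rep(2.5, 30))
  expect_equal(f_un$slope, f_eq$slope, tolerance = 1e-12)
  expect_equal(f_un$intercept, f_eq$intercept, tolerance = 1e-12)
  expect_error(fit_ols(pm2, weights = rep(-1, 30)), "positive")
  expect_error(fit_ols(paired_measurements(rep(1, 5), 1:5)), "constant")
  expect_error(fit_ols(paired_measurements(c(0, 1, 2), c(0, 1, 2)),
                       weights = "inverse_x_squared"), "nonzero")
})

test_that("wols gains precision under proportional error", {
  wins <- 0L
  for (seed in 1:200) {
    g <- generate_paired(synthetic_spec(
      80, intercept = 0, slope = 1,
      noise_y = list(model = "proportional_cv", magnitude = 0.08),
      distribution = "uniform", dist_params = c(10, 100), seed = seed))
    se_w <- fit_ols(g$pairs, "inverse_x_squared")$diagnostics$slope_se
    se_o <- fit_ols(g$pairs)$diagnostics$slope_se
    if (se_w < se_o) wins <- wins + 1L
  }
  expect_gte(wins / 200, 0.90)
})

test_that("deming matches a numerical minimizer of the errors-in-variables SSE", {
  sse <- function(par, x, y, lambda) {
    a <- par[1]; b <- par[2]
    xhat <- (x + lambda * b * (y - a)) / (1 + lambda * b^2)
    sum((x - xhat)^2 + lambda * (y - a - b * xhat)^2)
  }
  # 4-point toy, lambda = 1
  pm <- paired_measurements(c(0, 1, 2, 3), c(0.1, 0.9, 2.2, 2.9))
  fit <- fit_deming(pm, lambda = 1)
  prof1 <- function(b) sse(c(mean(pm$y) - b * mean(pm$x), b), pm$x, pm$y, 1)
  o <- optimize(prof1, c(0.5, 1.5), tol = 1e-12)
  expect_equal(fit$slope, o$minimum, tolerance = 1e-8)
  expect_equal(fit$intercept, mean(pm$y) - o$minimum * mean(pm$x),
               tolerance = 1e-8)
  # the closed form minimises the objective for other lambdas too;
  # profile oracle: the optimal intercept given b is ybar - b xbar, so a
  # 1-D golden-section search over b minimises the full SSE
  for (lambda in c(0.25, 2, 8)) {
    pmr <- make_line_pairs(25, a = 5, b = 1.2, sd = 4, seed = 100 + lambda)
    fitr <- fit_deming(pmr, lambda = lambda, ci_method = "analytic")
    prof <- function(b) {
      sse(c(mean(pmr$y) - b * mean(pmr$x), b), pmr$x, pmr$y, lambda)
    }
    orc <- optimize(prof, c(0.5, 2.5), tol = 1e-12)
    expect_equal(fitr$slope, orc$minimum, tolerance = 1e-7)
  }
})

test_that("deming limiting cases: identity, orthogonal, OLS and inverse regression", {
  x <- c(1, 2, 3, 4, 5)
  fit <- fit_deming(paired_measurements(x, x))
  expect_equal(fit$slope, 1, tolerance = 1e-12)
  expect_equal(fit$intercept, 0, tolerance = 1e-12)
  # lambda = 1 equals the spectral total-least-squares oracle
  pm <- make_line_pairs(40, a = 10, b = 0.9, sd = 5, seed = 12)
  fit1 <- fit_deming(pm, lambda = 1)
  orc <- tls_oracle(pm$x, pm$y)
  expect_equal(fit1$slope, orc$slope, tolerance = 1e-9)
  expect_equal(fit1$intercept, orc$intercept, tolerance = 1e-9)
  # lambda -> 0: no error in x, tends to OLS of y on x
  ols <- fit_ols(pm)
  fit0 <- fit_deming(pm, lambda = 1e-8, ci_method = "analytic")
  expect_equal(fit0$slope, ols$slope, tolerance = 1e-6)
  # lambda -> Inf: all error in x, tends to the inverse regression s_yy/s_xy
  fitI <- fit_deming(pm, lambda = 1e8, ci_method = "analytic")
  inv_slope <- var(pm$y) / cov(pm$x, pm$y)
  expect_equal(fitI$slope, inv_slope, tolerance = 1e-6)
  expect_error(fit_deming(pm, lambda = -1), "positive")
})

test_that("weighted deming converges and handles proportional error", {
  g <- generate_paired(synthetic_spec(
    100, intercept = 0, slope = 1.05,
    noise_x = list(model = "proportional_cv", magnitude = 0.04),
    noise_y = list(model = "proportional_cv", magnitude = 0.04),
    distribution = "uniform", dist_params = c(20, 200), seed = 42))
  fit <- fit_deming(g$pairs, weighted = TRUE)
  expect_equal(fit$method, "wdeming")
  expect_gt(fit$diagnostics$iterations, 0)
  expect_equal(fit$slope, 1.05, tolerance = 0.05)
  expect_true(fit$slope_ci[1] <= fit$slope && fit$slope <= fit$slope_ci[2])
  # nonpositive levels break the 1/xhat^2 weighting
  pmneg <- paired_measurements(c(-5, -1, 2, 4, 8), c(-5, -1, 2, 4, 8) * 1.1)
  expect_error(fit_deming(pmneg, weighted = TRUE), "positive")
})

test_that("passing-bablok equals the brute-force enumeration oracle", {
  # deterministic n=8 fixture checked field by field
  x <- c(1, 2, 3, 4, 5, 6, 7, 8)
  y <- c(1.1, 2.3, 2.8, 4.2, 5.1, 5.8, 7.3, 8.0)
  suppressWarnings(fit <- fit_passing_bablok(paired_measurements(x, y)))
  orc <- pb_oracle(x, y)
  expect_identical(fit$slope, orc$slope)
  expect_identical(fit$intercept, orc$intercept)
  expect_identical(sort(unname(fit$slope_ci)), sort(orc$slope_ci))
  expect_equal(fit$diagnostics$n_slopes, orc$n_slopes)
  # 50 random fixtures with ties and negative slopes mixed in
  set.seed(55)
  for (i in 1:50) {
    n <- sample(5:30, 1)
    x <- round(runif(n, 0, 20), sample(0:1, 1))   # induces x ties
    y <- round(0.5 + runif(1, 0.5, 2) * x + rnorm(n, 0, 2), 1)
    if (sd(x) == 0) next
    suppressWarnings(fit <- fit_passing_bablok(paired_measurements(x, y)))
    orc <- pb_oracle(x, y)
    expect_identical(fit$slope, orc$slope)
    expect_identical(fit$intercept, orc$intercept)
    expect_identical(sort(unname(fit$slope_ci)), sort(orc$slope_ci))
  }
})

test_that("theil-sen equals hand enumeration and the brute-force oracle", {
  # hand-enumerated: slopes {2, 0.5, 1, -1, 0.5, 2}, median 0.75;
  # intercepts {0, 1.25, -0.5, 0.75}, median 0.375
  pm <- paired_measurements(c(0, 1, 2, 3), c(0, 2, 1, 3))
  fit <- fit_theil_sen(pm)
  expect_equal(fit$slope, 0.75)
  expect_equal(fit$intercept, 0.375)
  # exact line
  x <- c(1, 2, 3, 4, 5)
  fit2 <- fit_theil_sen(paired_measurements(x, 2 * x + 1))
  expect_equal(fit2$slope, 2)
  expect_equal(fit2$intercept, 1)
  # random fixtures incl. duplicated x: tied pairs are skipped
  set.seed(66)
  for (i in 1:50) {
    n <- sample(4:30, 1)
    x <- round(runif(n, 0, 15), sample(0:1, 1))
    y <- 1 + runif(1, -1.5, 1.5) * x + rnorm(n, 0, 1.5)
    if (sd(x) == 0) next
    fit <- fit_theil_sen(paired_measurements(x, y))
    orc <- ts_oracle(x, y)
    expect_identical(fit$slope, orc$slope)
    expect_identical(fit$intercept, orc$intercept)
    expect_identical(unname(fit$slope_ci), orc$slope_ci)
  }
  expect_error(fit_theil_sen(paired_measurements(rep(2, 4), 1:4)),
               "tied|undefined")
})

test_that("pb large mode decodes pair indices correctly and tracks the exact fit", {
  # decoding covers every (i, j) pair exactly once
  n <- 30
  dec <- methodcompare:::decode_pair_index(seq_len(n * (n - 1) / 2), n)
  expect_equal(anyDuplicated(paste(dec$i, dec$j)), 0L)
  expect_true(all(dec$i < dec$j))
  expect_true(all(dec$j <= n))
  expect_equal(length(dec$i), choose(n, 2))
  # with all pairs retained (m = N) the estimate equals the exact one
  pm <- make_line_pairs(200, a = 5, b = 1.02, sd = 4, seed = 77)
  exact <- fit_passing_bablok(pm)
  for (seed in 1:5) {
    lg <- fit_passing_bablok(pm, large_mode = TRUE, seed = seed)
    expect_equal(lg$slope, exact$slope, tolerance = 1e-12)
  }
  # genuine subsampling (a fifth of the pairs) stays close to the exact
  # slope across seeds
  for (seed in 1:20) {
    lg <- fit_passing_bablok(pm, large_mode = TRUE, seed = seed,
                             max_pairs = 4000)
    expect_lt(abs(lg$slope - exact$slope), 0.01)
    expect_true(lg$diagnostics$subsampled)
  }
  expect_error(fit_passing_bablok(pm, large_mode = TRUE), "seed")
})

test_that("estimators are equivariant under positive affine transforms", {
  # OLS and Theil-Sen are fully affine-equivariant; Deming needs lambda
  # rescaled by (b/d)^2 to stay on the same errors-in-variables problem;
  # Passing-Bablok's -1-slope rules only commute with equal axis scalings
  check_eqv <- function(f0, f1, tr, tol = 1e-8) {
    d_over_b <- unname(tr["d"] / tr["b"])
    expect_equal(f1$slope, f0$slope * d_over_b, tolerance = tol)
    expect_equal(f1$intercept,
                 unname(tr["c"] + tr["d"] * f0$intercept -
                          f0$slope * d_over_b * tr["a"]),
                 tolerance = tol)
  }
  for (seed in 90:94) {
    pm <- make_line_pairs(20, a = 4, b = 1.3, sd = 3, seed = seed)
    for (tr in list(c(a = 2, b = 3, c = -1, d = 0.5),
                    c(a = 0, b = 0.2, c = 5, d = 4))) {
      px <- paired_measurements(tr["a"] + tr["b"] * pm$x,
                                tr["c"] + tr["d"] * pm$y)
      for (m in c("ols", "theil_sen")) {
        check_eqv(fit_method(pm, m), fit_method(px, m), tr)
      }
      check_eqv(fit_deming(pm, lambda = 1),
                fit_deming(px, lambda = unname((tr["b"] / tr["d"])^2)), tr)
    }
    tr_eq <- c(a = 2, b = 3, c = -1, d = 3)
    px <- paired_measurements(tr_eq["a"] + tr_eq["b"] * pm$x,
                              tr_eq["c"] + tr_eq["d"] * pm$y)
    check_eqv(fit_passing_bablok(pm), fit_passing_bablok(px), tr_eq)
  }
})

test_that("rank estimators resist contamination that breaks OLS", {
  clean <- make_line_pairs(200, a = 0, b = 1, sd = 1, seed = 14)
  xc <- clean$x; yc <- clean$y
  # gross high-leverage outliers: the largest-x decile shifted upward
  idx <- order(xc, decreasing = TRUE)[1:20]
  yc[idx] <- yc[idx] + 60
  dirty <- paired_measurements(xc, yc)
  expect_lt(abs(fit_passing_bablok(dirty)$slope -
                  fit_passing_bablok(clean)$slope), 0.02)
  expect_lt(abs(fit_theil_sen(dirty)$slope -
                  fit_theil_sen(clean)$slope), 0.02)
  expect_gt(abs(fit_ols(dirty)$slope - fit_ols(clean)$slope), 0.1)
})

test_that("bias flags derive exactly from the confidence intervals", {
  mk <- function(ai, bi) new_fit <- structure(
    list(method = "ols", intercept = mean(ai), intercept_ci = ai,
         slope = mean(bi), slope_ci = bi, n = 10, options = list(),
         diagnostics = list()), class = "mc_fit")
  # published cohort row: intercept CI (21.647, 63.094), slope (0.998, 1.014)
  b <- assess_bias(mk(c(21.647, 63.094), c(0.998, 1.014)))
  expect_true(b$systematic_bias)
  expect_false(b$proportional_bias)
  # slope CI (1.01, 1.028): proportional bias present
  b2 <- assess_bias(mk(c(2.086, 49.562), c(1.01, 1.028)))
  expect_true(b2$proportional_bias)
  b3 <- assess_bias(mk(c(-1, 1), c(0.9, 1.1)))
  expect_false(b3$systematic_bias)
  expect_false(b3$proportional_bias)
  expect_match(b3$narrative, "[Nn]o evidence")
})

test_that("the method-selection decision table follows the assumptions", {
  clean <- generate_paired(synthetic_spec(
    50, noise_y = list(model = "constant_sd", magnitude = 2),
    distribution = "uniform", dist_params = c(50, 150), seed = 8))
  rep_clean <- run_assumptions(clean$pairs)
  # force the no-outlier, homoscedastic branch deterministically
  rep_clean$heteroscedastic <- FALSE
  rep_clean$has_outliers <- FALSE
  expect_equal(select_method(rep_clean, 50)$methods, c("ols", "deming"))
  rep_h <- rep_clean; rep_h$heteroscedastic <- TRUE
  expect_equal(select_method(rep_h, 50)$methods, c("wols", "wdeming"))
  rep_o <- rep_clean; rep_o$has_outliers <- TRUE
  expect_equal(select_method(rep_o, 50)$methods,
               c("passing_bablok", "theil_sen"))
  # large-n switch replaces exact PB with the subsampling variant
  sel_large <- select_method(rep_o, 1e6)
  expect_equal(sel_large$methods, c("pb_large", "theil_sen"))
  expect_true(all(nzchar(unlist(select_method(rep_o, 50)$rationale))))
})
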