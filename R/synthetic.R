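#' Specification for synthetic paired measurements
#'
#' Defines the ground truth for a simulated method-comparison dataset:
#' true values t_i from a configurable distribution, a reference method
#' x_i = t_i + err_x and a test method y_i = a + b t_i + err_y, with
#' constant-SD or proportional-CV noise on each axis and optional
#' shift-contaminated outliers. The defaults emulate a term-pregnancy
#' birth-weight setting: log-normal true weights around 3300 g with a
#' coefficient of variation of about 15%.
#'
#' @param n Number of subjects (>= 3).
#' @param distribution \code{"lognormal"} (default) or \code{"uniform"}.
#' @param dist_params For lognormal: \code{c(meanlog, sdlog)} (default
#'   \code{c(log(3300), 0.15)}); for uniform: \code{c(min, max)}.
#' @param intercept,slope True line a, b relating y to the true values.
#' @param noise_x,noise_y Noise models: a list with \code{model}
#'   (\code{"constant_sd"} or \code{"proportional_cv"}) and
#'   \code{magnitude} (SD in measurement units, or CV as a fraction).
#' @param outlier_fraction Fraction of rows displaced (in \[0, 1)).
#' @param outlier_shift Displacement added to y for contaminated rows, in
#'   multiples of the SD of y.
#' @param seed Integer seed (required: no implicit global RNG state).
#' @return A list of class \code{"synthetic_spec"}.
#' @export
synthetic_spec <- function(n,
                           distribution = c("lognormal", "uniform"),
                           dist_params = NULL,
                           intercept = 0, slope = 1,
                           noise_x = list(model = "constant_sd",
                                          magnitude = 0),
                           noise_y = list(model = "constant_sd",
                                          magnitude = 0),
                           outlier_fraction = 0, outlier_shift = 10,
                           seed) {
  distribution <- match.arg(distribution)
  if (missing(seed)) stop("a seed is required")
  if (n < 3L) stop("n must be >= 3")
  if (is.null(dist_params)) {
    dist_params <- if (distribution == "lognormal") c(log(3300), 0.15)
    else c(2000, 4500)
  }
  for (nz in list(noise_x, noise_y)) {
    if (!nz$model %in% c("constant_sd", "proportional_cv")) {
      stop("noise model must be constant_sd or proportional_cv")
    }
    if (nz$magnitude < 0) stop("noise magnitude must be >= 0")
  }
  if (outlier_fraction < 0 || outlier_fraction >= 1) {
    stop("outlier_fraction must be in [0, 1)")
  }
  if (!is.finite(intercept) || !is.finite(slope)) {
    stop("intercept and slope must be finite")
  }
  structure(
    list(n = as.integer(n), distribution = distribution,
         dist_params = dist_params, intercept = intercept, slope = slope,
         noise_x = noise_x, noise_y = noise_y,
         outlier_fraction = outlier_fraction,
         outlier_shift = outlier_shift, seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

#' Generate paired measurements with known ground truth
#'
#' @param spec A [synthetic_spec()].
#' @return A list with \code{pairs} (a [paired_measurements()] object) and
#'   \code{truth}: the spec plus the true values, per-point noise draws
#'   and the logical outlier mask. The same seed reproduces the output
#'   bit for bit.
#' @examples
#' g <- generate_paired(synthetic_spec(50, slope = 1.05, intercept = 20,
#'   noise_y = list(model = "proportional_cv", magnitude = 0.05),
#'   seed = 7))
#' g$pairs$n
#' @export
generate_paired <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  withr::with_seed(spec$seed, {
    t <- switch(spec$distribution,
      lognormal = stats::rlnorm(spec$n, spec$dist_params[1],
                                spec$dist_params[2]),
      uniform = stats::runif(spec$n, spec$dist_params[1],
                             spec$dist_params[2])
    )
    draw_noise <- function(nz, center) {
      sd <- switch(nz$model,
                   constant_sd = rep(nz$magnitude, spec$n),
                   proportional_cv = nz$magnitude * abs(center))
      stats::rnorm(spec$n, 0, sd)
    }
    mu_y <- spec$intercept + spec$slope * t
    ex <- draw_noise(spec$noise_x, t)
    ey <- draw_noise(spec$noise_y, mu_y)
    x <- t + ex
    y <- mu_y + ey
    n_out <- floor(spec$outlier_fraction * spec$n)
    mask <- rep(FALSE, spec$n)
    if (n_out > 0) {
      idx <- sample(spec$n, n_out)
      mask[idx] <- TRUE
      y[idx] <- y[idx] + spec$outlier_shift * stats::sd(y)
    }
    list(pairs = paired_measurements(x, y),
         truth = list(spec = spec, true_values = t, noise_x = ex,
                      noise_y = ey, outlier_mask = mask))
  })
}

#' Generate a plausible fetal biometry table
#'
#' Draws correlated BPD/HC/AC/FL columns for term-pregnancy fetuses: a
#' latent fetal-size factor drives all four measurements, with
#' measurement-specific noise, and the draws are clamped inside the
#' Hadlock plausibility envelope so every row evaluates under all five
#' formulas without warnings. Intended as demo input for [efw_table()],
#' not as a reproduction of any particular cohort.
#'
#' @param n Number of fetuses (>= 1).
#' @param seed Integer seed.
#' @return A [method_table()] with columns \code{bpd}, \code{hc},
#'   \code{ac}, \code{fl} (cm).
#' @export
generate_biometry <- function(n, seed) {
  if (n < 1L) stop("n must be >= 1")
  if (missing(seed)) stop("a seed is required")
  withr::with_seed(seed, {
    size <- stats::rnorm(n)                    # latent term-size factor
    clamp <- function(v, lo, hi) pmin(pmax(v, lo), hi)
    bpd <- clamp(9.2 + 0.35 * size + stats::rnorm(n, 0, 0.15), 7.5, 10.8)
    hc <- clamp(33.5 + 1.1 * size + stats::rnorm(n, 0, 0.5), 29, 38)
    ac <- clamp(33.5 + 1.6 * size + stats::rnorm(n, 0, 0.8), 27, 42)
    fl <- clamp(7.2 + 0.25 * size + stats::rnorm(n, 0, 0.12), 6.0, 8.6)
    method_table(data.frame(bpd = bpd, hc = hc, ac = ac, fl = fl))
  })
}
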