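#' Hadlock estimated-fetal-weight formula coefficients
#'
#' The five Hadlock regression formulas predicting log10 of the estimated
#' fetal weight (grams) from ultrasound biometry in centimetres:
#' biparietal diameter (BPD), head circumference (HC), abdominal
#' circumference (AC) and femur length (FL). Coefficients are stored as
#' data constants, transcribed digit-for-digit from the original
#' publications (Hadlock et al. 1985 for I-IV; the BPD/AC two-parameter
#' model for V), with the full formula string kept beside each set for
#' audit.
#'
#' @format A named list; each element has \code{inputs} (required
#'   biometry fields), \code{terms} (named coefficient vector) and
#'   \code{formula_text}.
#' @export
hadlock_formulas <- list(
  hadlock1 = list(
    inputs = c("bpd", "hc", "ac", "fl"),
    terms = c(const = 1.3596, hc = 0.0064, ac = 0.0424, fl = 0.174,
              bpd_ac = 0.00061, ac_fl = -0.00386),
    formula_text = paste0("log10EFW = 1.3596 + 0.0064*HC + 0.0424*AC + ",
                          "0.174*FL + 0.00061*BPD*AC - 0.00386*AC*FL")
  ),
  hadlock2 = list(
    inputs = c("ac", "fl"),
    terms = c(const = 1.304, ac = 0.05281, fl = 0.1938, ac_fl = -0.004),
    formula_text = paste0("log10EFW = 1.304 + 0.05281*AC + 0.1938*FL - ",
                          "0.004*AC*FL")
  ),
  hadlock3 = list(
    inputs = c("bpd", "ac", "fl"),
    terms = c(const = 1.335, ac_fl = -0.0034, bpd = 0.0316, ac = 0.0457,
              fl = 0.1623),
    formula_text = paste0("log10EFW = 1.335 - 0.0034*AC*FL + 0.0316*BPD + ",
                          "0.0457*AC + 0.1623*FL")
  ),
  hadlock4 = list(
    inputs = c("hc", "ac", "fl"),
    terms = c(const = 1.326, ac_fl = -0.00326, hc = 0.0107, ac = 0.0438,
              fl = 0.158),
    formula_text = paste0("log10EFW = 1.326 - 0.00326*AC*FL + 0.0107*HC + ",
                          "0.0438*AC + 0.158*FL")
  ),
  hadlock5 = list(
    inputs = c("bpd", "ac"),
    terms = c(const = 1.1134, ac = 0.05845, ac2 = -0.000604,
              bpd2 = -0.007365, bpd_ac = 0.000595, bpd = 0.1694),
    formula_text = paste0("log10EFW = 1.1134 + 0.05845*AC - 0.000604*AC^2 ",
                          "- 0.007365*BPD^2 + 0.000595*BPD*AC + 0.1694*BPD")
  )
)

# biometric plausibility envelope (cm); values outside warn, not error
efw_envelope <- list(bpd = c(1, 12), hc = c(5, 40), ac = c(5, 45),
                     fl = c(0.5, 9))

#' Estimated fetal weight from one Hadlock formula
#'
#' Evaluates the requested Hadlock polynomial on biometry in centimetres
#' and returns both log10(EFW) and EFW in grams. Only the biometry fields
#' the formula uses are required (I: BPD, HC, AC, FL; II: AC, FL; III:
#' BPD, AC, FL; IV: HC, AC, FL; V: BPD, AC); extra fields are ignored.
#' Values outside the plausibility envelope (BPD 1-12, HC 5-40, AC 5-45,
#' FL 0.5-9 cm) trigger a warning, not an error. All arguments are
#' vectorised.
#'
#' @param formula_id One of \code{"hadlock1"} .. \code{"hadlock5"} (or
#'   1..5).
#' @param bpd,hc,ac,fl Biometry in cm; positive and finite where required.
#' @return A list of class \code{"efw_result"}: \code{formula_id},
#'   \code{log10_efw}, \code{efw_grams}.
#' @examples
#' compute_efw("hadlock4", hc = 33, ac = 33, fl = 7)$efw_grams
#' @export
compute_efw <- function(formula_id, bpd = NULL, hc = NULL, ac = NULL,
                        fl = NULL) {
  if (is.numeric(formula_id)) formula_id <- paste0("hadlock", formula_id)
  spec <- hadlock_formulas[[formula_id]]
  if (is.null(spec)) {
    stop("unknown formula_id '", formula_id, "'; expected hadlock1..hadlock5")
  }
  supplied <- list(bpd = bpd, hc = hc, ac = ac, fl = fl)
  vals <- list()
  for (f in spec$inputs) {
    v <- supplied[[f]]
    if (is.null(v)) {
      stop(formula_id, " requires ", toupper(f), " (inputs: ",
           paste(toupper(spec$inputs), collapse = ", "), ")")
    }
    v <- as.numeric(v)
    if (any(!is.finite(v)) || any(v <= 0)) {
      stop(toupper(f), " must be positive and finite (in cm)")
    }
    env <- efw_envelope[[f]]
    if (any(v < env[1] | v > env[2])) {
      warning(toupper(f), " outside the plausibility envelope [",
              env[1], ", ", env[2], "] cm")
    }
    vals[[f]] <- v
  }
  tm <- spec$terms
  term_value <- function(name) {
    switch(name,
           const = 1,
           bpd = vals$bpd, hc = vals$hc, ac = vals$ac, fl = vals$fl,
           ac2 = vals$ac^2, bpd2 = vals$bpd^2,
           bpd_ac = vals$bpd * vals$ac, ac_fl = vals$ac * vals$fl,
           stop("unknown term: ", name))
  }
  log10_efw <- 0
  for (nm in names(tm)) log10_efw <- log10_efw + tm[[nm]] * term_value(nm)
  structure(list(formula_id = formula_id, log10_efw = log10_efw,
                 efw_grams = 10^log10_efw),
            class = "efw_result")
}

#' @export
print.efw_result <- function(x, ...) {
  cat(sprintf("%s: EFW %s g (log10 %s)\n", x$formula_id,
              paste(signif(x$efw_grams, 6), collapse = ", "),
              paste(signif(x$log10_efw, 6), collapse = ", ")))
  invisible(x)
}

#' Append Hadlock EFW columns to a biometry table
#'
#' For each requested formula, evaluates [compute_efw()] row-wise on the
#' biometry columns (named \code{bpd}, \code{hc}, \code{ac}, \code{fl},
#' case-insensitive) and appends one EFW column (grams) named after the
#' formula.
#'
#' @param biometry_table A [method_table()] with the required biometry
#'   columns for every requested formula.
#' @param formulas Character or integer vector of formulas (default all
#'   five).
#' @return A [method_table()] with the original columns plus one EFW
#'   column per formula, row-aligned with the input.
#' @export
efw_table <- function(biometry_table, formulas = 1:5) {
  stopifnot(inherits(biometry_table, "method_table"))
  if (is.numeric(formulas)) formulas <- paste0("hadlock", formulas)
  dat <- biometry_table$data
  lookup <- stats::setNames(names(dat), tolower(names(dat)))
  getcol <- function(f) if (f %in% names(lookup)) dat[[lookup[[f]]]] else NULL
  out <- dat
  for (fid in formulas) {
    spec <- hadlock_formulas[[fid]]
    if (is.null(spec)) stop("unknown formula: ", fid)
    missing_cols <- spec$inputs[!spec$inputs %in% names(lookup)]
    if (length(missing_cols)) {
      stop(fid, " needs biometry column(s) not present in the table: ",
           paste(toupper(missing_cols), collapse = ", "))
    }
    res <- compute_efw(fid, bpd = getcol("bpd"), hc = getcol("hc"),
                       ac = getcol("ac"), fl = getcol("fl"))
    out[[fid]] <- res$efw_grams
  }
  method_table(out, subject_ids = biometry_table$subject_ids,
               n_dropped = biometry_table$n_dropped)
}
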