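#' Fit a linear calibration curve for colorimetric quantification
#'
#' Ordinary least-squares line absorbance = slope * concentration +
#' intercept, the standard way a phenol-sulfuric (OD490) total-carbohydrate
#' standard curve is quantified.
#'
#' @param standards A data frame with numeric columns `concentration`
#'   (mg/mL) and `absorbance`, at least two distinct concentrations.
#'
#' @return An object of class `calibration_curve` with fields `slope`,
#'   `intercept`, `r_squared` and `n_standards`.
#' @examples
#' std <- tibble::tibble(concentration = c(0, 0.25, 0.5, 0.75, 1),
#'                       absorbance = c(0.02, 0.22, 0.41, 0.62, 0.81))
#' fit_calibration(std)
#' @export
fit_calibration <- function(standards) {
  if (!is.data.frame(standards) ||
      !all(c("concentration", "absorbance") %in% names(standards))) {
    stop("`standards` needs columns `concentration` and `absorbance`",
         call. = FALSE)
  }
  conc <- standards$concentration
  abs_ <- standards$absorbance
  stopifnot(is.numeric(conc), is.numeric(abs_), all(is.finite(conc)),
            all(is.finite(abs_)))
  if (length(unique(conc)) < 2) {
    stop("degenerate standards: at least 2 distinct concentrations required",
         call. = FALSE)
  }
  fit <- stats::lm(abs_ ~ conc)
  cf <- stats::coef(fit)
  pred <- stats::fitted(fit)
  r2 <- if (stats::sd(abs_) == 0) 1 else r_squared(abs_, pred)
  structure(list(slope = unname(cf[["conc"]]),
                 intercept = unname(cf[["(Intercept)"]]),
                 r_squared = r2,
                 n_standards = length(conc)),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf(
    "Calibration curve: absorbance = %.6g * conc + %.6g (R2 = %.4f, n = %d)\n",
    x$slope, x$intercept, x$r_squared, x$n_standards))
  invisible(x)
}

#' Invert a calibration curve
#'
#' Converts absorbance readings back to concentrations:
#' dilution * (A - intercept) / slope. Values below the blank come out
#' negative; they are returned as computed (not clipped) with attribute
#' `below_limit` marking them.
#'
#' @param curve A [fit_calibration()] result.
#' @param absorbance Numeric absorbance reading(s).
#' @param dilution Dilution factor applied to the sample before reading
#'   (> 0). Default 1.
#'
#' @return Concentration(s) in mg/mL with logical attribute `below_limit`.
#' @examples
#' cal <- fit_calibration(tibble::tibble(concentration = c(0, 1),
#'                                       absorbance = c(0.02, 0.82)))
#' concentration_from_absorbance(cal, 0.42, dilution = 2)
#' @export
concentration_from_absorbance <- function(curve, absorbance, dilution = 1) {
  stopifnot(inherits(curve, "calibration_curve"), is.numeric(absorbance),
            is.numeric(dilution), all(dilution > 0))
  if (curve$slope == 0) {
    stop("calibration curve with zero slope is not invertible",
         call. = FALSE)
  }
  conc <- dilution * (absorbance - curve$intercept) / curve$slope
  attr(conc, "below_limit") <- conc < 0
  conc
}

#' Alpha-amylase inhibition rate
#'
#' Percent inhibition of starch hydrolysis computed as
#' `[1 - (A - B)/C] * 100`, where `A` is the absorbance of the sample
#' reaction (sample + enzyme + substrate), `B` the sample background
#' (sample without enzyme) and `C` the uninhibited enzyme-substrate
#' control. That reading of A, B and C is the conventional one for
#' DNS-based inhibition assays; the formula itself is agnostic to it.
#' Values above 100% or below 0% occur in real assays and are returned as
#' computed, with logical attribute `out_of_range` marking them.
#'
#' @param A Sample-reaction absorbance(s), finite and non-negative.
#' @param B Sample-background absorbance(s).
#' @param C Control absorbance(s), strictly positive.
#'
#' @return Inhibition rate(s) in percent.
#' @examples
#' amylase_inhibition(A = 0.55, B = 0.15, C = 0.80) # 50
#' @export
amylase_inhibition <- function(A, B, C) {
  stopifnot(is.numeric(A), is.numeric(B), is.numeric(C))
  if (!all(is.finite(A) & A >= 0) || !all(is.finite(B) & B >= 0) ||
      !all(is.finite(C))) {
    stop("absorbance readings must be finite and non-negative",
         call. = FALSE)
  }
  if (any(C <= 0)) stop("control absorbance C must be > 0", call. = FALSE)
  pct <- (1 - (A - B) / C) * 100
  attr(pct, "out_of_range") <- pct < 0 | pct > 100
  pct
}
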