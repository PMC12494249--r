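#' IFCC/NGSP conversion constants
#'
#' The two HbA1c reporting scales are related by the affine master equation
#' `NGSP% = 0.09148 x IFCC(mmol/mol) + 2.152`. The constants are exposed as
#' configuration so laboratory-specific calibrations can be substituted.
#'
#' @param slope Percent per mmol/mol; must be positive.
#' @param intercept Percent.
#' @return An object of class `unit_system`.
#' @export
unit_system <- function(slope = 0.09148, intercept = 2.152) {
  if (!is.numeric(slope) || slope <= 0) {
    stop("unit_system: `slope` must be positive", call. = FALSE)
  }
  structure(list(slope = slope, intercept = intercept), class = "unit_system")
}

#' Convert IFCC mmol/mol to NGSP percent
#'
#' @param value HbA1c in mmol/mol (vectorised).
#' @param us A [unit_system()].
#' @return HbA1c in NGSP %.
#' @export
ngsp_from_ifcc <- function(value, us = unit_system()) {
  us$slope * value + us$intercept
}

#' Convert NGSP percent to IFCC mmol/mol
#'
#' Exact algebraic inverse of [ngsp_from_ifcc()].
#'
#' @param value HbA1c in NGSP %.
#' @param us A [unit_system()].
#' @return HbA1c in mmol/mol.
#' @export
ifcc_from_ngsp <- function(value, us = unit_system()) {
  (value - us$intercept) / us$slope
}

#' Within-individual CV before and after IFCC-to-NGSP conversion
#'
#' Fits the model-based CV on the original mmol/mol scale and again after
#' converting every value to NGSP %. Because the conversion is affine with a
#' positive intercept, the within-patient SD scales by the slope while the
#' mean gains the intercept, so the CV on the percent scale is strictly
#' smaller whenever the within-patient SD is positive: the CV is not
#' invariant under this change of units.
#'
#' @param cohort Cleaned lab-record tibble in mmol/mol.
#' @param us A [unit_system()].
#' @param engine Variance-components engine, `"reml"` or `"moments"`.
#' @return A list with `cv_ifcc` and `cv_ngsp_converted` (both
#'   `cv_estimate` objects).
#' @export
cv_under_conversion <- function(cohort, us = unit_system(),
                                engine = c("reml", "moments")) {
  engine <- match.arg(engine)
  fit_fun <- if (engine == "reml") fit_components_reml else fit_components_moments
  orig <- cv_from_components(fit_fun(cohort))
  conv <- cohort
  conv$value <- ngsp_from_ifcc(cohort$value, us)
  conv$unit <- "percent"
  converted <- cv_from_components(fit_fun(conv))
  list(cv_ifcc = orig, cv_ngsp_converted = converted)
}
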