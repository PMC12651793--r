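#' Coefficient set for estimated glycemic index formulas
#'
#' Bundles every fixed constant used by the two eGI predictors and the
#' starch-conversion arithmetic: the single-point formula
#' \code{eGI = 39.21 + 0.803 * H90}, the kinetics + macronutrient formula
#' \code{eGI = A + (S60/S120) * HI - 0.26 * Protein + 0.54 * Fat - 0.43 * Fiber},
#' the carbohydrate threshold that selects the intercept A, and the
#' anhydroglucose mass factor 0.9 (162/180) that converts free glucose back
#' to starch equivalents. All defaults can be overridden, e.g. to explore
#' sensitivity, but the defaults are the published values.
#'
#' @param goni_intercept intercept of the single-point (Goni-style) formula.
#' @param goni_slope slope on H90 in the single-point formula.
#' @param protein_coef coefficient on protein (g/100 g) in the kinetic formula.
#' @param fat_coef coefficient on fat (g/100 g).
#' @param fiber_coef coefficient on fiber (g/100 g).
#' @param a_high intercept A used for high-carbohydrate foods.
#' @param a_low intercept A used otherwise.
#' @param carb_threshold carbohydrate content (g/100 g) above which
#'   \code{a_high} applies (strictly greater than).
#' @param starch_glucose_factor mass ratio converting glucose released to
#'   anhydroglucose (starch) equivalents.
#'
#' @return An object of class \code{"egi_coefficients"}: a named list of the
#'   nine constants.
#' @examples
#' egi_coefficients()
#' egi_coefficients(carb_threshold = 50)
#' @export
egi_coefficients <- function(goni_intercept = 39.21,
                             goni_slope = 0.803,
                             protein_coef = -0.26,
                             fat_coef = 0.54,
                             fiber_coef = -0.43,
                             a_high = 30,
                             a_low = 15,
                             carb_threshold = 55,
                             starch_glucose_factor = 0.9) {
  coefs <- list(
    goni_intercept = as.numeric(goni_intercept),
    goni_slope = as.numeric(goni_slope),
    protein_coef = as.numeric(protein_coef),
    fat_coef = as.numeric(fat_coef),
    fiber_coef = as.numeric(fiber_coef),
    a_high = as.numeric(a_high),
    a_low = as.numeric(a_low),
    carb_threshold = as.numeric(carb_threshold),
    starch_glucose_factor = as.numeric(starch_glucose_factor)
  )
  bad <- names(coefs)[!vapply(coefs, function(x) length(x) == 1L && is.finite(x), logical(1))]
  if (length(bad) > 0L) {
    stop("egi_coefficients: non-finite or non-scalar value for: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (coefs$starch_glucose_factor <= 0) {
    stop("egi_coefficients: starch_glucose_factor must be positive", call. = FALSE)
  }
  structure(coefs, class = "egi_coefficients")
}

#' @export
print.egi_coefficients <- function(x, ...) {
  cat("eGI coefficient set\n")
  cat(sprintf("  single-point: eGI = %.2f + %.3f * H90\n", x$goni_intercept, x$goni_slope))
  cat(sprintf("  kinetic:      eGI = A + (S60/S120)*HI %+.2f*Protein %+.2f*Fat %+.2f*Fiber\n",
              x$protein_coef, x$fat_coef, x$fiber_coef))
  cat(sprintf("  A = %g if carbohydrate > %g g/100 g, else %g\n",
              x$a_high, x$carb_threshold, x$a_low))
  cat(sprintf("  anhydroglucose factor = %g\n", x$starch_glucose_factor))
  invisible(x)
}

as_egi_coefficients <- function(x) {
  if (inherits(x, "egi_coefficients")) return(x)
  if (is.list(x)) return(do.call(egi_coefficients, x))
  stop("expected an 'egi_coefficients' object or a named list", call. = FALSE)
}
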