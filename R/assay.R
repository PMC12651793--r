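# Reducing-sugar assay plumbing: glucose standard curve and the conversion
# of released glucose to percent starch hydrolysed.

#' Fit a glucose standard curve
#'
#' Ordinary least squares line through (concentration, absorbance) pairs from
#' a dinitrosalicylic-acid assay read at 520 nm. Standards span 0-1 mg/mL.
#'
#' @param concentration glucose concentrations in mg/mL, within [0, 1].
#' @param absorbance matched absorbance readings.
#' @return Object of class \code{"glucose_calibration"}: \code{slope}
#'   (absorbance per mg/mL), \code{intercept} (absorbance), \code{r_squared}.
#' @examples
#' fit_glucose_calibration(c(0, 0.5, 1), c(0.02, 0.42, 0.82))
#' @export
fit_glucose_calibration <- function(concentration, absorbance) {
  concentration <- as.numeric(concentration)
  absorbance <- as.numeric(absorbance)
  stopifnot(length(concentration) == length(absorbance),
            length(concentration) >= 2L)
  if (any(concentration < 0 | concentration > 1)) {
    stop("fit_glucose_calibration: standards must lie in [0, 1] mg/mL",
         call. = FALSE)
  }
  if (length(unique(concentration)) < 2L) {
    stop("fit_glucose_calibration: all concentrations identical (degenerate design)",
         call. = FALSE)
  }
  fit <- stats::lm(absorbance ~ concentration)
  slope <- unname(stats::coef(fit)[2L])
  if (!is.finite(slope) || slope <= 0) {
    stop("fit_glucose_calibration: fitted slope is not positive; check standards",
         call. = FALSE)
  }
  tss <- sum((absorbance - mean(absorbance))^2)
  r2 <- if (tss == 0) 1 else 1 - sum(stats::resid(fit)^2) / tss
  structure(
    list(slope = slope,
         intercept = unname(stats::coef(fit)[1L]),
         r_squared = r2),
    class = "glucose_calibration"
  )
}

#' @export
print.glucose_calibration <- function(x, ...) {
  cat(sprintf("Glucose standard curve: A520 = %.4f * conc + %.4f (R^2 = %.4f)\n",
              x$slope, x$intercept, x$r_squared))
  invisible(x)
}

#' Glucose concentration from absorbance
#'
#' Inverts the standard curve and applies a dilution factor. Slightly
#' negative results (blank-level readings) are clipped to zero with a warning.
#'
#' @param a520 absorbance at 520 nm.
#' @param cal a \code{\link{fit_glucose_calibration}} result.
#' @param dilution dilution factor applied before reading (>= 1).
#' @return Glucose concentration in mg/mL.
#' @export
glucose_from_absorbance <- function(a520, cal, dilution = 1) {
  stopifnot(inherits(cal, "glucose_calibration"), cal$slope > 0)
  if (any(dilution < 1)) {
    stop("glucose_from_absorbance: dilution must be >= 1", call. = FALSE)
  }
  conc <- (as.numeric(a520) - cal$intercept) / cal$slope * dilution
  if (any(conc < 0)) {
    warning("negative glucose concentration(s) clipped to 0", call. = FALSE)
    conc <- pmax(conc, 0)
  }
  conc
}

#' Percent starch hydrolysed from glucose released
#'
#' Converts the mass of glucose released at a time point to the percentage of
#' total starch hydrolysed:
#' \code{hydrolysis % = g_t * 0.9 / ts * 100}, where 0.9 is the
#' anhydroglucose mass ratio (162/180) folding free glucose back into
#' polymeric starch equivalents. The result is not clipped here; the curve
#' constructor applies the [0, 100] policy.
#'
#' @param g_t glucose mass released (same units as \code{ts}).
#' @param ts total starch mass; must be positive.
#' @param coefs an \code{\link{egi_coefficients}} set (supplies the 0.9 factor).
#' @return Hydrolysis percentage (unclipped).
#' @examples
#' starch_hydrolysis_pct(0.5, 0.9)  # 50
#' @export
starch_hydrolysis_pct <- function(g_t, ts, coefs = egi_coefficients()) {
  coefs <- as_egi_coefficients(coefs)
  g_t <- as.numeric(g_t)
  if (any(ts <= 0)) {
    stop("starch_hydrolysis_pct: total starch must be positive", call. = FALSE)
  }
  if (any(g_t < 0)) {
    stop("starch_hydrolysis_pct: glucose mass must be non-negative", call. = FALSE)
  }
  g_t * coefs$starch_glucose_factor / ts * 100
}
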