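#' Construct a starch-hydrolysis time-course
#'
#' A hydrolysis curve is the cumulative percent of starch hydrolysed at a set
#' of sampling times (minutes from the start of the intestinal phase, t = 0 at
#' simulated intestinal fluid addition). Values slightly outside [0, 100]
#' (within 2 percentage points, typical of reducing-sugar assay noise) are
#' clipped into range with a warning; larger violations are rejected as unit
#' errors.
#'
#' @param food_id short identifier of the food.
#' @param times sampling times in minutes; strictly increasing, first >= 0.
#' @param values hydrolysis percentages, one per time.
#' @param digestion_model \code{"dynamic"} (peristalsis-simulating rig) or
#'   \code{"static"} (shaking water bath).
#' @param replicate integer replicate label.
#'
#' @return Object of class \code{"hydrolysis_curve"} with fields
#'   \code{food_id}, \code{digestion_model}, \code{replicate}, \code{times},
#'   \code{values}, and \code{clipped} (logical: was any value clipped).
#' @examples
#' hydrolysis_curve("rice", c(0, 15, 30, 45, 60, 90, 120),
#'                  c(10, 35, 55, 70, 80, 90, 95))
#' @export
hydrolysis_curve <- function(food_id, times, values,
                             digestion_model = c("dynamic", "static"),
                             replicate = 1L) {
  digestion_model <- match.arg(digestion_model)
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(times) < 2L) {
    stop("hydrolysis_curve: need at least 2 time points", call. = FALSE)
  }
  if (length(values) != length(times)) {
    stop("hydrolysis_curve: times and values must have equal length", call. = FALSE)
  }
  if (anyNA(times) || anyNA(values)) {
    stop("hydrolysis_curve: NA in times or values", call. = FALSE)
  }
  if (times[1] < 0 || any(diff(times) <= 0)) {
    stop("hydrolysis_curve: times must be strictly increasing and start at >= 0",
         call. = FALSE)
  }
  clipped <- clip_hydrolysis(values)
  structure(
    list(food_id = as.character(food_id),
         digestion_model = digestion_model,
         replicate = as.integer(replicate),
         times = times,
         values = clipped$values,
         clipped = clipped$clipped),
    class = "hydrolysis_curve"
  )
}

# Clipping policy: values in (100, 102] or [-2, 0) -> clipped to [0, 100]
# with a warning; beyond +/-2 rejected.
clip_hydrolysis <- function(values) {
  if (any(values < -2 | values > 102)) {
    stop("hydrolysis values outside [-2, 102]: likely a unit error (",
         paste(signif(values[values < -2 | values > 102], 4), collapse = ", "),
         ")", call. = FALSE)
  }
  out <- values
  clip <- values < 0 | values > 100
  if (any(clip)) {
    out <- pmin(pmax(values, 0), 100)
    warning(sum(clip), " hydrolysis value(s) outside [0, 100] clipped (assay noise)",
            call. = FALSE)
  }
  list(values = out, clipped = any(clip))
}

#' @export
print.hydrolysis_curve <- function(x, ...) {
  cat(sprintf("Hydrolysis curve: %s [%s, replicate %d], %d points over %g-%g min\n",
              x$food_id, x$digestion_model, x$replicate,
              length(x$times), min(x$times), max(x$times)))
  print(stats::setNames(round(x$values, 2), x$times))
  invisible(x)
}

#' Interpolated hydrolysis percentage at a time point
#'
#' Linear interpolation between the bracketing samples; exact on grid points.
#' Extrapolation outside the sampled range is refused — with seven samples per
#' curve there is no basis for it.
#'
#' @param curve a \code{\link{hydrolysis_curve}}.
#' @param t time(s) in minutes, each within \code{range(curve$times)}.
#' @return Hydrolysis percentage(s) at \code{t}.
#' @examples
#' cv <- hydrolysis_curve("x", c(0, 120), c(10, 90))
#' value_at(cv, 60)  # 50
#' @export
value_at <- function(curve, t) {
  stopifnot(inherits(curve, "hydrolysis_curve"))
  t <- as.numeric(t)
  if (any(t < min(curve$times)) || any(t > max(curve$times))) {
    stop(sprintf("value_at: t outside sampled range [%g, %g]; no extrapolation",
                 min(curve$times), max(curve$times)), call. = FALSE)
  }
  stats::approx(curve$times, curve$values, xout = t, method = "linear",
                ties = "ordered")$y
}

#' Area under a hydrolysis curve by the composite trapezoid rule
#'
#' Integrates the piecewise-linear curve over \code{[t_start, t_end]} on the
#' sampled grid, interpolating the window endpoints when they fall between
#' samples. Units are percent-minutes.
#'
#' @param curve a \code{\link{hydrolysis_curve}}.
#' @param t_start,t_end integration window in minutes; must lie within the
#'   sampled range with \code{t_start < t_end}. Defaults to the full range.
#' @return AUC in %.min.
#' @examples
#' cv <- hydrolysis_curve("x", c(0, 120), c(0, 100))
#' auc_trapezoid(cv)  # 6000
#' @export
auc_trapezoid <- function(curve, t_start = min(curve$times),
                          t_end = max(curve$times)) {
  stopifnot(inherits(curve, "hydrolysis_curve"))
  if (!(t_start < t_end)) {
    stop("auc_trapezoid: need t_start < t_end (zero-width window has no area)",
         call. = FALSE)
  }
  if (t_start < min(curve$times) || t_end > max(curve$times)) {
    stop("auc_trapezoid: window outside sampled range", call. = FALSE)
  }
  inner <- curve$times > t_start & curve$times < t_end
  tt <- c(t_start, curve$times[inner], t_end)
  vv <- value_at(curve, tt)
  sum(diff(tt) * (utils::head(vv, -1) + utils::tail(vv, -1)) / 2)
}

#' Hydrolysis index (HI) of a curve
#'
#' The hydrolysis index summarises a digestion time-course as the area under
#' the hydrolysis-vs-time curve, expressed relative to a reference:
#' \code{HI = 100 * AUC(curve) / AUC(reference)}. By default the reference is
#' the ideal instantaneous-digestion curve (constant 100% over the window),
#' which bounds HI to [0, 100] and puts it on the scale the kinetic eGI
#' formula expects. Pass an explicit reference curve (e.g. white bread
#' digested alongside the sample) for the classic food-relative HI.
#'
#' @param curve a \code{\link{hydrolysis_curve}}.
#' @param reference optional reference \code{\link{hydrolysis_curve}}; must
#'   have positive AUC on the window.
#' @param t_start,t_end window in minutes (defaults 0 and 120, the intestinal
#'   sampling span).
#' @return Dimensionless HI.
#' @examples
#' cv <- hydrolysis_curve("x", c(0, 120), c(0, 100))
#' hydrolysis_index(cv)  # 50
#' @export
hydrolysis_index <- function(curve, reference = NULL, t_start = 0, t_end = 120) {
  auc <- auc_trapezoid(curve, t_start, t_end)
  if (is.null(reference)) {
    return(100 * auc / ((t_end - t_start) * 100))
  }
  stopifnot(inherits(reference, "hydrolysis_curve"))
  ref_auc <- auc_trapezoid(reference, t_start, t_end)
  if (ref_auc <= 0) {
    stop("hydrolysis_index: reference curve has zero AUC on the window",
         call. = FALSE)
  }
  100 * auc / ref_auc
}

#' Kinetic and index summaries of a hydrolysis curve
#'
#' Extracts the quantities both eGI formulas consume: S60, S90 (= H90), S120
#' (cumulative percent hydrolysed at 60, 90, 120 min), the trapezoid AUC over
#' the window, and the hydrolysis index under the default normalization.
#'
#' @param curve a \code{\link{hydrolysis_curve}} spanning the window.
#' @param t_start,t_end summary window in minutes (defaults 0, 120).
#' @return A list of class \code{"hydrolysis_metrics"}: \code{s60},
#'   \code{s90}, \code{s120}, \code{auc}, \code{hi}.
#' @examples
#' cv <- hydrolysis_curve("x", c(0, 15, 30, 45, 60, 90, 120),
#'                        c(10, 35, 55, 70, 80, 90, 95))
#' hydrolysis_metrics(cv)
#' @export
hydrolysis_metrics <- function(curve, t_start = 0, t_end = 120) {
  structure(
    list(s60 = value_at(curve, 60),
         s90 = value_at(curve, 90),
         s120 = value_at(curve, 120),
         auc = auc_trapezoid(curve, t_start, t_end),
         hi = hydrolysis_index(curve, NULL, t_start, t_end)),
    class = "hydrolysis_metrics"
  )
}

#' Pointwise mean of replicate curves
#'
#' Replicate digestion runs are averaged on their common sampling grid before
#' any metric is extracted, mirroring mean-of-triplicates reporting. All
#' curves must share food, digestion model, and time grid.
#'
#' @param curves list of \code{\link{hydrolysis_curve}} objects.
#' @return A single \code{\link{hydrolysis_curve}} (replicate label 0).
#' @export
average_replicates <- function(curves) {
  stopifnot(length(curves) >= 1L,
            all(vapply(curves, inherits, logical(1), "hydrolysis_curve")))
  if (length(curves) == 1L) return(curves[[1L]])
  ref <- curves[[1L]]
  for (cv in curves[-1L]) {
    if (!identical(cv$food_id, ref$food_id) ||
        !identical(cv$digestion_model, ref$digestion_model)) {
      stop("average_replicates: curves mix foods or digestion models", call. = FALSE)
    }
    if (!isTRUE(all.equal(cv$times, ref$times))) {
      stop("average_replicates: replicate time grids differ for ", ref$food_id,
           call. = FALSE)
    }
  }
  vals <- rowMeans(vapply(curves, `[[`, numeric(length(ref$times)), "values"))
  hydrolysis_curve(ref$food_id, ref$times, vals, ref$digestion_model,
                   replicate = 0L)
}
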