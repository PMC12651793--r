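#' Intercept constant A of the kinetic eGI formula
#'
#' The kinetic formula uses a two-level intercept keyed to carbohydrate
#' density: A = 30 when carbohydrate content strictly exceeds 55 g/100 g,
#' A = 15 otherwise. The boundary value 55.0 itself maps to 15 (strict
#' "exceeds").
#'
#' @param carbohydrate carbohydrate content in g/100 g; non-negative.
#' @param coefs an \code{\link{egi_coefficients}} set.
#' @return \code{coefs$a_high} or \code{coefs$a_low} (vectorized).
#' @examples
#' choose_A(71.8)  # 30
#' choose_A(3.4)   # 15
#' @export
choose_A <- function(carbohydrate, coefs = egi_coefficients()) {
  coefs <- as_egi_coefficients(coefs)
  carbohydrate <- as.numeric(carbohydrate)
  if (any(carbohydrate < 0)) {
    stop("choose_A: carbohydrate must be non-negative", call. = FALSE)
  }
  ifelse(carbohydrate > coefs$carb_threshold, coefs$a_high, coefs$a_low)
}

#' Single-point estimated glycemic index
#'
#' The classic predictor from the 90-minute hydrolysis value alone:
#' \code{eGI = 39.21 + 0.803 * H90}.
#'
#' @param s90 percent starch hydrolysed at 90 min (H90), in [0, 100].
#' @param coefs an \code{\link{egi_coefficients}} set.
#' @return Estimated glycemic index (vectorized).
#' @examples
#' egi_goni(0)    # 39.21
#' egi_goni(50)   # 79.36
#' @export
egi_goni <- function(s90, coefs = egi_coefficients()) {
  coefs <- as_egi_coefficients(coefs)
  s90 <- as.numeric(s90)
  if (any(s90 < 0 | s90 > 100)) {
    stop("egi_goni: H90 must lie in [0, 100]", call. = FALSE)
  }
  coefs$goni_intercept + coefs$goni_slope * s90
}

#' Kinetics + macronutrient estimated glycemic index
#'
#' The predictor combining hydrolysis kinetics with food composition:
#' \deqn{eGI = A + (S60 / S120) \times HI - 0.26 \cdot Protein
#'       + 0.54 \cdot Fat - 0.43 \cdot Fiber}
#' where S60 and S120 are cumulative percent hydrolysed at 60 and 120 min,
#' HI is the hydrolysis index (0-100 scale), and A is
#' \code{\link{choose_A}} of the carbohydrate content. The ratio S60/S120
#' discounts HI for slow digesters (for a monotone curve it is at most 1).
#' The result is returned unclamped; negative values indicate the flag,
#' not an error.
#'
#' @param metrics a \code{\link{hydrolysis_metrics}} object (or list with
#'   \code{s60}, \code{s120}, \code{hi}).
#' @param food one food row: list or single-row data.frame with
#'   \code{carbohydrate}, \code{protein}, \code{fat}, \code{fiber} (g/100 g).
#' @param coefs an \code{\link{egi_coefficients}} set.
#' @return Estimated glycemic index.
#' @examples
#' m <- list(s60 = 80, s120 = 80, hi = 50)
#' f <- list(carbohydrate = 60, protein = 0, fat = 0, fiber = 0)
#' egi_new(m, f)  # 30 + 1 * 50 = 80
#' @export
egi_new <- function(metrics, food, coefs = egi_coefficients()) {
  coefs <- as_egi_coefficients(coefs)
  if (is.null(metrics$s120) || metrics$s120 <= 0) {
    stop("egi_new: S120 must be positive (S60/S120 undefined on an undigested curve)",
         call. = FALSE)
  }
  comp <- as.numeric(c(food$carbohydrate, food$protein, food$fat, food$fiber))
  if (length(comp) != 4L || anyNA(comp) || any(comp < 0)) {
    stop("egi_new: food must carry non-negative carbohydrate, protein, fat, fiber",
         call. = FALSE)
  }
  choose_A(comp[1L], coefs) +
    (metrics$s60 / metrics$s120) * metrics$hi +
    coefs$protein_coef * comp[2L] +
    coefs$fat_coef * comp[3L] +
    coefs$fiber_coef * comp[4L]
}

#' Compute both eGI predictions for a panel of foods
#'
#' For each food: selects its curves under the requested digestion model,
#' averages replicates pointwise, extracts the kinetic summaries
#' (\code{\link{hydrolysis_metrics}}), and evaluates both predictors. Foods
#' without any matching curve are skipped and listed in the result's
#' \code{"skipped"} attribute rather than raising an error, so one missing
#' run does not abort a panel.
#'
#' @param foods food table (see \code{\link{load_food_table}}).
#' @param curves list of \code{\link{hydrolysis_curve}} objects.
#' @param digestion_model which model's curves to use.
#' @param coefs an \code{\link{egi_coefficients}} set.
#' @param t_start,t_end metric window in minutes (defaults 0, 120).
#' @return A data.frame with one row per scored food: \code{food_id},
#'   \code{digestion_model}, \code{s60}, \code{s90}, \code{s120}, \code{auc},
#'   \code{hi}, \code{a_constant}, \code{egi_goni}, \code{egi_new},
#'   \code{flags} (semicolon-joined, "" if none); attribute \code{"skipped"}
#'   holds the food_ids without curves.
#' @export
compute_panel <- function(foods, curves,
                          digestion_model = c("dynamic", "static"),
                          coefs = egi_coefficients(),
                          t_start = 0, t_end = 120) {
  digestion_model <- match.arg(digestion_model)
  coefs <- as_egi_coefficients(coefs)
  stopifnot(is.data.frame(foods), nrow(foods) >= 1L)
  by_food <- split(
    Filter(function(cv) cv$digestion_model == digestion_model, curves),
    vapply(Filter(function(cv) cv$digestion_model == digestion_model, curves),
           `[[`, character(1), "food_id")
  )
  rows <- list()
  skipped <- character(0)
  for (i in seq_len(nrow(foods))) {
    fid <- foods$food_id[i]
    cvs <- by_food[[fid]]
    if (is.null(cvs) || length(cvs) == 0L) {
      skipped <- c(skipped, fid)
      next
    }
    mean_curve <- average_replicates(cvs)
    m <- hydrolysis_metrics(mean_curve, t_start, t_end)
    flags <- character(0)
    if (any(vapply(cvs, `[[`, logical(1), "clipped"))) {
      flags <- c(flags, "clipped_input")
    }
    e_new <- egi_new(m, foods[i, ], coefs)
    if (e_new < 0) flags <- c(flags, "negative_egi")
    rows[[length(rows) + 1L]] <- data.frame(
      food_id = fid,
      digestion_model = digestion_model,
      s60 = m$s60, s90 = m$s90, s120 = m$s120,
      auc = m$auc, hi = m$hi,
      a_constant = choose_A(foods$carbohydrate[i], coefs),
      egi_goni = egi_goni(m$s90, coefs),
      egi_new = e_new,
      flags = paste(flags, collapse = ";")
    )
  }
  out <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(food_id = character(0), digestion_model = character(0),
               s60 = numeric(0), s90 = numeric(0), s120 = numeric(0),
               auc = numeric(0), hi = numeric(0), a_constant = numeric(0),
               egi_goni = numeric(0), egi_new = numeric(0),
               flags = character(0))
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}
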