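#' Percent deviation of a prediction from human GI
#'
#' \code{deviation = (GI_human - eGI) / GI_human * 100}: positive when the
#' predictor underestimates the human value, negative when it overestimates.
#' Reported tables round to one decimal; this function returns full
#' precision.
#'
#' @param human_gi human glycemic index; must be positive.
#' @param egi predicted glycemic index.
#' @return Deviation percentage (vectorized).
#' @examples
#' deviation_pct(27, 52)  # -92.59...
#' @export
deviation_pct <- function(human_gi, egi) {
  human_gi <- as.numeric(human_gi)
  egi <- as.numeric(egi)
  if (any(human_gi <= 0)) {
    stop("deviation_pct: human_gi must be positive", call. = FALSE)
  }
  (human_gi - egi) / human_gi * 100
}

#' Ordinary least squares line and Pearson correlation
#'
#' Regresses predicted eGI (y) on human GI (x) — the orientation under which
#' the published panel coefficients reproduce — and reports the sample
#' Pearson correlation.
#'
#' @param x human GI values (length >= 3, not constant).
#' @param y predicted eGI values, same length.
#' @return List with \code{slope}, \code{intercept}, \code{pearson_r}.
#' @examples
#' ols_line(c(1, 2, 3), c(2, 4, 6))  # slope 2, intercept 0, r 1
#' @export
ols_line <- function(x, y) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) {
    stop("ols_line: need at least 3 paired values", call. = FALSE)
  }
  if (stats::sd(x) == 0) {
    stop("ols_line: x is constant (degenerate design)", call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  r <- if (stats::sd(y) == 0) NA_real_ else stats::cor(x, y)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       pearson_r = r)
}

#' Validate an eGI column against human GI
#'
#' Builds the full prediction-vs-reference report for one predictor:
#' per-food deviation plus the OLS slope/intercept and Pearson r of eGI on
#' human GI. Regression fields are \code{NA} when fewer than 3 foods are
#' paired.
#'
#' @param foods food table rows with \code{food_id} and positive
#'   \code{human_gi} for every entry of \code{egi}.
#' @param egi data.frame with columns \code{food_id} and \code{egi}.
#' @return Object of class \code{"validation_report"}: \code{n_foods},
#'   \code{per_food} (data.frame \code{food_id}, \code{human_gi}, \code{egi},
#'   \code{deviation}), \code{slope}, \code{intercept}, \code{pearson_r}.
#' @examples
#' tbl <- food_panel()
#' validate_panel(tbl, data.frame(food_id = tbl$food_id, egi = tbl$egi_goni))
#' @export
validate_panel <- function(foods, egi) {
  stopifnot(is.data.frame(foods), is.data.frame(egi),
            all(c("food_id", "egi") %in% names(egi)))
  idx <- match(egi$food_id, foods$food_id)
  if (anyNA(idx)) {
    stop("validate_panel: food_id not in the food table: ",
         paste(egi$food_id[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  human <- foods$human_gi[idx]
  if (anyNA(human)) {
    stop("validate_panel: human_gi missing for: ",
         paste(egi$food_id[is.na(human)], collapse = ", "), call. = FALSE)
  }
  per_food <- data.frame(
    food_id = egi$food_id,
    human_gi = human,
    egi = egi$egi,
    deviation = deviation_pct(human, egi$egi)
  )
  n <- nrow(per_food)
  line <- if (n >= 3L && stats::sd(human) > 0) {
    ols_line(human, egi$egi)
  } else {
    list(slope = NA_real_, intercept = NA_real_, pearson_r = NA_real_)
  }
  structure(
    list(n_foods = n, per_food = per_food,
         slope = line$slope, intercept = line$intercept,
         pearson_r = line$pearson_r),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("Validation report over %d foods\n", x$n_foods))
  if (!is.na(x$slope)) {
    cat(sprintf("  eGI = %.4f * humanGI + %.2f (Pearson r = %.2f)\n",
                x$slope, x$intercept, x$pearson_r))
  } else {
    cat("  regression not computed (fewer than 3 paired foods)\n")
  }
  pf <- x$per_food
  pf$deviation <- round(pf$deviation, 1)
  print(pf, row.names = FALSE)
  invisible(x)
}
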