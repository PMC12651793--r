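# Readers and writers for the two interchange files: a food composition
# table (one row per food, per-100 g macronutrients plus human GI) and a
# long-format hydrolysis time-course table. Dialect: comma-separated, UTF-8,
# dot decimal, mandatory header.

FOOD_REQUIRED_COLS <- c("food_id", "name", "carbohydrate", "protein",
                        "fat", "fiber", "human_gi")
FOOD_NUMERIC_COLS <- c("carbohydrate", "protein", "fat", "fiber",
                       "human_gi", "total_starch")
CURVE_REQUIRED_COLS <- c("food_id", "digestion_model", "replicate",
                         "time_min", "hydrolysis_pct")

parse_numeric_col <- function(raw, col, what) {
  x <- suppressWarnings(as.numeric(raw))
  bad <- which(is.na(x) & !is.na(raw) & trimws(raw) != "" & raw != "NA")
  if (length(bad) > 0L) {
    stop(sprintf("%s: non-numeric value '%s' in column '%s', row %d",
                 what, raw[bad[1L]], col, bad[1L]), call. = FALSE)
  }
  x
}

#' Read a food composition table
#'
#' Loads a CSV with one row per food: identity, per-100 g macronutrient
#' composition, human GI, and optionally the total starch per serving (only
#' needed when converting raw glucose measurements). Extra columns — for
#' example transcribed eGI columns — are preserved untouched.
#'
#' @param path path to a CSV with header
#'   \code{food_id,name,carbohydrate,protein,fat,fiber,human_gi[,total_starch]}.
#' @return A data.frame with validated columns, one row per food, input order
#'   preserved.
#' @examples
#' foods <- load_food_table(system.file("extdata", "table2.csv",
#'                                      package = "starchdx"))
#' head(foods)
#' @export
load_food_table <- function(path) {
  if (!file.exists(path)) {
    stop("load_food_table: file not found: ", path, call. = FALSE)
  }
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, fileEncoding = "UTF-8")
  missing_cols <- setdiff(FOOD_REQUIRED_COLS, names(raw))
  if (length(missing_cols) > 0L) {
    stop("load_food_table: missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(raw) == 0L) return(raw)
  for (col in intersect(FOOD_NUMERIC_COLS, names(raw))) {
    raw[[col]] <- parse_numeric_col(raw[[col]], col, "load_food_table")
  }
  # extra columns (e.g. transcribed eGI values) become numeric when they
  # parse cleanly; otherwise they stay character
  for (col in setdiff(names(raw), c(FOOD_NUMERIC_COLS, "food_id", "name"))) {
    num <- suppressWarnings(as.numeric(raw[[col]]))
    if (!anyNA(num[!is.na(raw[[col]]) & trimws(raw[[col]]) != ""])) {
      raw[[col]] <- num
    }
  }
  for (col in c("carbohydrate", "protein", "fat", "fiber")) {
    if (any(raw[[col]] < 0, na.rm = TRUE)) {
      stop("load_food_table: negative values in column '", col, "'",
           call. = FALSE)
    }
  }
  if (any(!is.na(raw$human_gi) & raw$human_gi <= 0)) {
    stop("load_food_table: human_gi must be positive where present",
         call. = FALSE)
  }
  if (any(!nzchar(trimws(raw$name)))) {
    stop("load_food_table: empty food name", call. = FALSE)
  }
  rownames(raw) <- NULL
  raw
}

#' Read hydrolysis time-courses from long-format CSV
#'
#' Each row is one sampled point; rows are grouped into curves by
#' (food_id, digestion_model, replicate) and sorted by time. Values must lie
#' in [-2, 102]; the usual clipping policy (see
#' \code{\link{hydrolysis_curve}}) then applies.
#'
#' @param path path to a CSV with header
#'   \code{food_id,digestion_model,replicate,time_min,hydrolysis_pct}.
#' @return A list of \code{\link{hydrolysis_curve}} objects, in first-seen
#'   key order.
#' @export
load_curves <- function(path) {
  if (!file.exists(path)) {
    stop("load_curves: file not found: ", path, call. = FALSE)
  }
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, fileEncoding = "UTF-8")
  missing_cols <- setdiff(CURVE_REQUIRED_COLS, names(raw))
  if (length(missing_cols) > 0L) {
    stop("load_curves: missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(raw) == 0L) return(list())
  raw$time_min <- parse_numeric_col(raw$time_min, "time_min", "load_curves")
  raw$hydrolysis_pct <- parse_numeric_col(raw$hydrolysis_pct,
                                          "hydrolysis_pct", "load_curves")
  raw$replicate <- parse_numeric_col(raw$replicate, "replicate", "load_curves")
  bad_model <- setdiff(unique(raw$digestion_model), c("dynamic", "static"))
  if (length(bad_model) > 0L) {
    stop("load_curves: unknown digestion_model: ",
         paste(bad_model, collapse = ", "), call. = FALSE)
  }
  if (any(raw$hydrolysis_pct < -2 | raw$hydrolysis_pct > 102)) {
    stop("load_curves: hydrolysis_pct outside [-2, 102]; likely a unit error",
         call. = FALSE)
  }
  key <- paste(raw$food_id, raw$digestion_model, raw$replicate, sep = "\r")
  dup <- duplicated(paste(key, raw$time_min, sep = "\r"))
  if (any(dup)) {
    stop(sprintf("load_curves: duplicated time point %g for (%s, %s, replicate %s)",
                 raw$time_min[dup][1L], raw$food_id[dup][1L],
                 raw$digestion_model[dup][1L], raw$replicate[dup][1L]),
         call. = FALSE)
  }
  lapply(split(raw, factor(key, levels = unique(key))), function(g) {
    g <- g[order(g$time_min), ]
    hydrolysis_curve(g$food_id[1L], g$time_min, g$hydrolysis_pct,
                     g$digestion_model[1L], as.integer(g$replicate[1L]))
  }) |> unname()
}

#' Write a list of curves to the long-format CSV dialect
#'
#' @param curves list of \code{\link{hydrolysis_curve}} objects.
#' @param path output path.
#' @return Invisibly, the path.
#' @export
write_curves <- function(curves, path) {
  stopifnot(length(curves) >= 1L,
            all(vapply(curves, inherits, logical(1), "hydrolysis_curve")))
  rows <- do.call(rbind, lapply(curves, function(cv) {
    data.frame(food_id = cv$food_id, digestion_model = cv$digestion_model,
               replicate = cv$replicate, time_min = cv$times,
               hydrolysis_pct = cv$values)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Write the combined eGI report
#'
#' One row per food with composition, human GI, both eGI predictions and
#' their percent deviations from human GI (rounded to one decimal), followed
#' by comment footer lines giving the OLS slope, intercept and Pearson r of
#' each predictor against human GI.
#'
#' @param results data.frame with columns \code{food_id}, \code{egi_goni},
#'   \code{egi_new} (as produced by \code{\link{compute_panel}}, or
#'   transcribed values).
#' @param foods food table (see \code{\link{load_food_table}}) supplying
#'   composition and human GI for every food in \code{results}.
#' @param path output path.
#' @return Invisibly, the two \code{\link{validate_panel}} reports
#'   (\code{$goni}, \code{$new}).
#' @export
write_egi_report <- function(results, foods, path) {
  if (is.null(results) || nrow(results) == 0L) {
    stop("write_egi_report: no results to write", call. = FALSE)
  }
  stopifnot(all(c("food_id", "egi_goni", "egi_new") %in% names(results)))
  idx <- match(results$food_id, foods$food_id)
  if (anyNA(idx)) {
    stop("write_egi_report: food(s) missing from the composition table: ",
         paste(results$food_id[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  ff <- foods[idx, ]
  rep_goni <- validate_panel(ff, data.frame(food_id = results$food_id,
                                            egi = results$egi_goni))
  rep_new <- validate_panel(ff, data.frame(food_id = results$food_id,
                                           egi = results$egi_new))
  out <- data.frame(
    food_id = results$food_id,
    name = ff$name,
    carbohydrate = ff$carbohydrate,
    protein = ff$protein,
    fat = ff$fat,
    fiber = ff$fiber,
    human_gi = ff$human_gi,
    egi_goni = round(results$egi_goni, 1),
    deviation_goni = round(rep_goni$per_food$deviation, 1),
    egi_new = round(results$egi_new, 1),
    deviation_new = round(rep_new$per_food$deviation, 1)
  )
  con <- tryCatch(file(path, "w", encoding = "UTF-8"),
                  error = function(e) stop("write_egi_report: cannot open ",
                                           path, call. = FALSE))
  on.exit(close(con))
  utils::write.csv(out, con, row.names = FALSE, quote = TRUE)
  fmt <- function(label, r) {
    if (is.na(r$slope)) return(sprintf("# %s: regression not computed (n < 3)", label))
    sprintf("# %s: slope=%.4f intercept=%.2f r=%.2f n=%d",
            label, r$slope, r$intercept, r$pearson_r, r$n_foods)
  }
  writeLines(c(fmt("egi_goni vs human_gi", rep_goni),
               fmt("egi_new vs human_gi", rep_new)), con)
  invisible(list(goni = rep_goni, new = rep_new))
}

#' The packaged 14-food composition and GI panel
#'
#' Composition (g/100 g), human GI (China Food Composition Table, 6th ed.),
#' and the two published eGI columns for 14 common foods spanning cereals,
#' legumes, roots, fruits and dairy. The per-food hydrolysis inputs behind
#' the eGI columns are not part of the panel; the transcribed eGI values are
#' used for validating the regression and deviation machinery.
#'
#' @return A data.frame with 14 rows and columns \code{food_id}, \code{name},
#'   \code{carbohydrate}, \code{protein}, \code{fat}, \code{fiber},
#'   \code{human_gi}, \code{egi_goni}, \code{egi_new}.
#' @examples
#' food_panel()
#' @export
food_panel <- function() {
  load_food_table(system.file("extdata", "table2.csv", package = "starchdx",
                              mustWork = TRUE))
}
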