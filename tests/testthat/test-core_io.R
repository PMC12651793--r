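test_that("packaged 14-food panel loads with the printed composition", {
  tbl <- food_panel()
  expect_equal(nrow(tbl), 14L)
  expect_equal(tbl$name[1], "Lotus root powder (pure)")
  expect_equal(tbl$carbohydrate[1], 93.0)
  expect_equal(tbl$name[14], "Milk (pure)")
  expect_equal(tbl$human_gi[14], 27)
  expect_true(all(c("egi_goni", "egi_new") %in% names(tbl)))
})

test_that("food table loader enforces schema and parses strictly", {
  # header-only file -> empty result
  path <- write_tmp_csv(tiny_foods()[0, ], name = "empty.csv")
  expect_equal(nrow(load_food_table(path)), 0L)

  # missing required column named in the error
  broken <- tiny_foods(); broken$fiber <- NULL
  path <- write_tmp_csv(broken, name = "nofiber.csv")
  expect_error(load_food_table(path), "fiber")

  # non-numeric cell reported with row and column
  bad <- tiny_foods(); bad$protein <- as.character(bad$protein)
  bad$protein[2] <- "lots"
  path <- write_tmp_csv(bad, name = "badnum.csv")
  expect_error(load_food_table(path), "protein.*row 2")

  expect_error(load_food_table(file.path(tempdir(), "nope.csv")), "not found")

  neg <- tiny_foods(); neg$fat[1] <- -1
  expect_error(load_food_table(write_tmp_csv(neg, name = "neg.csv")),
               "negative")
})

test_that("food table round-trips and is stable under column reordering", {
  foods <- tiny_foods()
  path <- write_tmp_csv(foods, name = "rt.csv")
  back <- load_food_table(path)
  expect_equal(back$food_id, foods$food_id)
  for (col in c("carbohydrate", "protein", "fat", "fiber", "human_gi")) {
    expect_equal(back[[col]], foods[[col]])
  }
  shuffled <- foods[, rev(names(foods))]
  back2 <- load_food_table(write_tmp_csv(shuffled, name = "rt2.csv"))
  expect_equal(back2$food_id, foods$food_id)  # row order preserved
  expect_equal(back2$human_gi, foods$human_gi)
})

test_that("curve loader groups rows into per-replicate curves", {
  rows <- data.frame(
    food_id = "rice", digestion_model = "dynamic", replicate = 1L,
    time_min = grid7,
    hydrolysis_pct = first_order_value(grid7, 10, 95, 0.03)
  )
  path <- write_tmp_csv(rows, name = "cv1.csv")
  curves <- load_curves(path)
  expect_length(curves, 1L)
  expect_s3_class(curves[[1]], "hydrolysis_curve")
  expect_length(curves[[1]]$times, 7L)

  # two replicates -> two curves
  rows2 <- rbind(rows, transform(rows, replicate = 2L))
  expect_length(load_curves(write_tmp_csv(rows2, name = "cv2.csv")), 2L)

  # unsorted times are sorted on load
  shuf <- rows[sample(nrow(rows)), ]
  cv <- load_curves(write_tmp_csv(shuf, name = "cv3.csv"))[[1]]
  expect_equal(cv$times, grid7)

  # duplicate time for one replicate is rejected
  dup <- rbind(rows, rows[5, ])
  expect_error(load_curves(write_tmp_csv(dup, name = "cv4.csv")),
               "duplicated time")

  # gross out-of-range value rejected as unit error
  bad <- rows; bad$hydrolysis_pct[3] <- 150
  expect_error(load_curves(write_tmp_csv(bad, name = "cv5.csv")),
               "unit error")
})

test_that("mild out-of-range hydrolysis values are clipped with a warning", {
  expect_warning(cv <- hydrolysis_curve("x", c(0, 60, 120), c(-1.5, 50, 101)),
                 "clipped")
  expect_equal(cv$values, c(0, 50, 100))
  expect_true(cv$clipped)
  expect_error(hydrolysis_curve("x", c(0, 60), c(0, 103)), "unit error")
})

test_that("curves round-trip through the long-format dialect", {
  curves <- list(fo_curve(10, 95, 0.03, "a"),
                 fo_curve(5, 60, 0.02, "b", "static"))
  path <- file.path(tempdir(), "cvs_rt.csv")
  write_curves(curves, path)
  back <- load_curves(path)
  expect_length(back, 2L)
  expect_equal(back[[1]]$values, curves[[1]]$values)
  expect_equal(back[[2]]$digestion_model, "static")
})

test_that("the combined report writes rows plus regression footer", {
  tbl <- food_panel()
  results <- data.frame(food_id = tbl$food_id,
                        egi_goni = tbl$egi_goni, egi_new = tbl$egi_new)
  path <- file.path(tempdir(), "report.csv")
  reps <- write_egi_report(results, tbl, path)
  lines <- readLines(path)
  milk <- lines[grepl("Milk \\(pure\\)", lines)]
  expect_match(milk, "-92.6")  # published single-point deviation for milk
  footer <- lines[startsWith(lines, "#")]
  expect_length(footer, 2L)
  expect_match(footer[1], "slope=0.7573")
  expect_match(footer[2], "slope=0.9519")
  expect_equal(reps$goni$n_foods, 14L)

  # a perfect prediction has zero deviation
  one <- data.frame(food_id = "rice", egi_goni = 82, egi_new = 82)
  p2 <- file.path(tempdir(), "report1.csv")
  write_egi_report(one, tbl, p2)
  expect_match(readLines(p2)[2], ",0,")

  expect_error(write_egi_report(results[0, ], tbl, path), "no results")
})
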