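# Shared fixtures: small in-code tables and curve builders used across the
# suite. All synthetic; nothing is read from outside the package.

grid7 <- c(0, 15, 30, 45, 60, 90, 120)

# noiseless first-order curve on the standard grid
fo_curve <- function(c0, c_inf, k, food_id = "x",
                     digestion_model = "dynamic", replicate = 1L,
                     times = grid7) {
  hydrolysis_curve(food_id, times,
                   first_order_value(times, c0, c_inf, k),
                   digestion_model, replicate)
}

# minimal valid food table
tiny_foods <- function() {
  data.frame(
    food_id = c("a", "b", "c"),
    name = c("Food A", "Food B", "Food C"),
    carbohydrate = c(70, 40, 10),
    protein = c(8, 12, 1),
    fat = c(1, 9, 0.5),
    fiber = c(2, 5, 1),
    human_gi = c(75, 50, 35)
  )
}

write_tmp_csv <- function(df, dir = tempdir(), name = "tmp.csv") {
  path <- file.path(dir, name)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  path
}

# independent OLS oracle: explicit normal equations, no lm()
ols_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  sxx <- sum(x^2); sxy <- sum(x * y); syy <- sum(y^2)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- (sy - slope * sx) / n
  r <- (n * sxy - sx * sy) /
    sqrt((n * sxx - sx^2) * (n * syy - sy^2))
  list(slope = slope, intercept = intercept, pearson_r = r)
}

# independent AUC oracle: per-segment symbolic integration of the linear
# interpolant a*t + b
auc_oracle <- function(times, values, t_start, t_end) {
  total <- 0
  for (i in seq_len(length(times) - 1L)) {
    t1 <- max(times[i], t_start); t2 <- min(times[i + 1L], t_end)
    if (t2 <= t1) next
    a <- (values[i + 1L] - values[i]) / (times[i + 1L] - times[i])
    b <- values[i] - a * times[i]
    total <- total + a / 2 * (t2^2 - t1^2) + b * (t2 - t1)
  }
  total
}
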