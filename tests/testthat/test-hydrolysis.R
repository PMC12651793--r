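test_that("glucose standard curve fits an OLS line with sane guards", {
  cal <- fit_glucose_calibration(c(0, 1), c(0, 0.80))
  expect_equal(cal$slope, 0.80)
  expect_equal(cal$intercept, 0.00)
  expect_equal(cal$r_squared, 1.0)

  cal2 <- fit_glucose_calibration(c(0, 0.5, 1), c(0.02, 0.42, 0.82))
  expect_equal(cal2$slope, 0.80)
  expect_equal(cal2$intercept, 0.02)

  expect_error(fit_glucose_calibration(c(0.5, 0.5), c(0.4, 0.5)),
               "degenerate")
  expect_error(fit_glucose_calibration(c(0, 2), c(0, 1)), "\\[0, 1\\]")
})

test_that("absorbance inverts through the standard curve with dilution", {
  cal <- fit_glucose_calibration(c(0, 1), c(0, 0.80))
  expect_equal(glucose_from_absorbance(0.40, cal), 0.50)
  expect_equal(glucose_from_absorbance(0.40, cal, dilution = 4), 2.00)
  expect_equal(glucose_from_absorbance(cal$intercept, cal), 0)
  expect_warning(out <- glucose_from_absorbance(-0.1, cal), "clipped")
  expect_equal(out, 0)
  expect_error(glucose_from_absorbance(0.4, cal, dilution = 0.5), ">= 1")
})

test_that("starch hydrolysis percent applies the anhydroglucose factor", {
  expect_equal(starch_hydrolysis_pct(0, 1), 0)
  expect_equal(starch_hydrolysis_pct(1 / 0.9, 1), 100)
  expect_equal(starch_hydrolysis_pct(0.5, 0.9), 50)
  expect_error(starch_hydrolysis_pct(0.5, 0), "positive")
  # linear in glucose, inverse-linear in starch
  g <- runif(20, 0, 1)
  expect_equal(starch_hydrolysis_pct(3 * g, 1), 3 * starch_hydrolysis_pct(g, 1))
  expect_equal(starch_hydrolysis_pct(g, 2), starch_hydrolysis_pct(g, 1) / 2)
})

test_that("value_at interpolates linearly, exactly on grid, never beyond", {
  cv <- hydrolysis_curve("x", c(0, 120), c(10, 90))
  expect_equal(value_at(cv, 60), 50)
  cv2 <- hydrolysis_curve("x", c(0, 45, 90, 120), c(5, 40, 73.4, 80))
  expect_equal(value_at(cv2, 90), 73.4)  # on-grid identity
  expect_error(value_at(cv2, 150), "extrapolation|range")
  expect_error(value_at(cv2, -1), "extrapolation|range")
  # monotone between bracketing samples
  ts <- seq(45, 90, by = 5)
  expect_true(all(diff(value_at(cv2, ts)) >= 0))
})

test_that("trapezoid AUC matches segment-wise symbolic integration", {
  flat <- hydrolysis_curve("x", c(0, 120), c(100, 100))
  expect_equal(auc_trapezoid(flat), 12000)
  lin <- hydrolysis_curve("x", c(0, 120), c(0, 100))
  expect_equal(auc_trapezoid(lin), 6000)
  expect_error(auc_trapezoid(lin, 60, 60), "zero-width")
  expect_error(auc_trapezoid(lin, 0, 130), "outside")

  set.seed(11)
  for (i in 1:20) {
    n <- sample(3:8, 1)
    tt <- sort(sample(0:120, n))
    vv <- runif(n, 0, 100)
    cv <- hydrolysis_curve("x", tt, vv)
    w <- sort(runif(2, min(tt), max(tt)))
    if (diff(w) < 1) next
    expect_equal(auc_trapezoid(cv, w[1], w[2]),
                 auc_oracle(tt, vv, w[1], w[2]), tolerance = 1e-12)
  }
})

test_that("hydrolysis index normalizes AUC to the instantaneous reference", {
  flat <- hydrolysis_curve("x", c(0, 120), c(100, 100))
  expect_equal(hydrolysis_index(flat), 100)
  lin <- hydrolysis_curve("x", c(0, 120), c(0, 100))
  expect_equal(hydrolysis_index(lin), 50)
  zero <- hydrolysis_curve("x", c(0, 120), c(0, 0))
  expect_equal(hydrolysis_index(zero), 0)
  expect_error(hydrolysis_index(lin, reference = zero), "zero AUC")

  # explicit reference: sample relative to a slower food
  ref <- hydrolysis_curve("bread", c(0, 120), c(0, 50))
  expect_equal(hydrolysis_index(lin, reference = ref), 200)

  # scale invariance under the default reference
  set.seed(12)
  for (lam in runif(5, 0.05, 1)) {
    vv <- runif(7, 0, 100)
    cv <- hydrolysis_curve("x", grid7, vv)
    cvl <- hydrolysis_curve("x", grid7, lam * vv)
    expect_equal(hydrolysis_index(cvl), lam * hydrolysis_index(cv),
                 tolerance = 1e-12)
  }
})

test_that("hydrolysis_metrics bundles the summaries both formulas need", {
  cv <- fo_curve(10, 95, 0.03)
  m <- hydrolysis_metrics(cv)
  expect_equal(m$s60, value_at(cv, 60))
  expect_equal(m$s90, value_at(cv, 90))
  expect_equal(m$s120, value_at(cv, 120))
  expect_equal(m$hi, m$auc / 120)
  expect_true(m$s60 <= m$s120)  # monotone curve
})

test_that("first-order fit recovers generating parameters exactly on noiseless data", {
  cases <- list(c(10, 95, 0.03), c(0, 50, 0.005), c(20, 99, 0.08),
                c(5, 30, 0.05))
  for (p in cases) {
    fit <- fit_first_order(fo_curve(p[1], p[2], p[3]))
    expect_lt(abs(fit$c0 - p[1]), 1e-6 * max(p[1], 1))
    expect_lt(abs(fit$c_inf - p[2]) / p[2], 1e-6)
    expect_lt(abs(fit$k - p[3]) / p[3], 1e-6)
    expect_lt(fit$rss, 1e-10)
    expect_length(fit$flags, 0L)
  }
})

test_that("first-order fit degrades gracefully on degenerate input", {
  flat <- hydrolysis_curve("x", grid7, rep(40, 7))
  fit <- fit_first_order(flat)
  expect_equal(fit$c0, 40)
  expect_equal(fit$c_inf, 40)
  expect_equal(fit$k, 0)
  expect_true("k_indeterminate" %in% fit$flags)

  short <- hydrolysis_curve("x", c(0, 15, 30), c(10, 20, 30))
  expect_error(fit_first_order(short), "at least 4")
  narrow <- hydrolysis_curve("x", c(0, 10, 20, 30), c(10, 15, 20, 25))
  expect_error(fit_first_order(narrow), "60 minutes")
})

test_that("rate constant is recovered without bias from noisy replicates", {
  cfg <- simulation_config(seed = 5, c0 = 10, c_inf = 95, k = 0.03,
                           noise_sd = 2, n_replicates = 200)
  ks <- vapply(simulate_curve(cfg, "mc"),
               function(cv) fit_first_order(cv)$k, numeric(1))
  expect_lt(mean(abs(ks - 0.03)), 0.005)
})
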