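# Serial dilutions, 4PL fitting, validated-active classification.

test_that("serial_dilution reproduces the standard 3-fold series", {
  s <- serial_dilution(0.5, 3, 7)
  expect_equal(s$concentrations, 0.5 / 3^(0:6), tolerance = 1e-15)
  expect_equal(
    format_concentration(s$concentrations),
    c("0.5", "0.167", "0.056", "0.0185", "0.0062", "0.0021", "0.00069")
  )
  expect_equal(serial_dilution(7, 10, 1)$concentrations, 7)
  expect_equal(serial_dilution(1, 2, 3)$concentrations, c(1, 0.5, 0.25))
  expect_error(serial_dilution(0, 3, 7), class = "hcs_domain_error")
  expect_error(serial_dilution(0.5, 1, 7), class = "hcs_domain_error")
  expect_error(serial_dilution(0.5, 3, 0), class = "hcs_domain_error")
})

test_that("fit_sigmoid recovers noiseless 4PL parameters to 1e-6 relative", {
  conc <- serial_dilution(0.5, 3, 7)$concentrations
  truth <- list(bottom = 0, top = 100, ec50 = 0.05, hill = 1)
  y <- logistic4(conc, truth$bottom, truth$top, truth$ec50, truth$hill)
  fit <- fit_sigmoid(conc, y)
  expect_true(fit$converged)
  expect_lt(abs(fit$ec50 - 0.05) / 0.05, 1e-6)
  expect_lt(abs(fit$hill - 1), 1e-6)
  expect_lt(abs(fit$top - 100) / 100, 1e-6)
  expect_lt(abs(fit$bottom), 1e-4)
})

test_that("fit_sigmoid handles flat data, missing points and short series", {
  conc <- serial_dilution(0.5, 3, 7)$concentrations
  fit <- fit_sigmoid(conc, rep(25, 7))
  expect_true(fit$degenerate)
  expect_equal(fit$top, fit$bottom)
  # missing (cytotoxic) responses are excluded, fit still succeeds on 5 points
  y <- logistic4(conc, 0, 80, 0.03, 1.5)
  y[1:2] <- NA
  fit <- fit_sigmoid(conc, y)
  expect_equal(fit$n_used, 5)
  expect_lt(abs(fit$ec50 - 0.03) / 0.03, 1e-4)
  expect_error(fit_sigmoid(conc[1:3], c(1, 2, 3)), class = "hcs_insufficient_data_error")
  expect_error(
    fit_sigmoid(conc, c(1, 2, 3, NA, NA, NA, NA)),
    class = "hcs_insufficient_data_error"
  )
  expect_error(fit_sigmoid(-conc, rep(1, 7)), class = "hcs_domain_error")
})

test_that("EC50 recovery: median relative error <= 10% at noise SD 2", {
  conc <- serial_dilution(0.5, 3, 7)$concentrations
  truth <- list(bottom = 0, top = 100, ec50 = 0.05, hill = 1)
  rel_err <- vapply(1:100, function(seed) {
    pts <- simulate_dose_series(truth, conc, noise_sd = 2, seed = seed)
    fit <- fit_sigmoid(conc, pts$activity)
    abs(fit$ec50 - truth$ec50) / truth$ec50
  }, numeric(1))
  expect_lte(median(rel_err), 0.10)
})

test_that("fitted EC50 is equivariant under concentration rescaling", {
  conc <- serial_dilution(0.5, 3, 7)$concentrations
  y <- logistic4(conc, 5, 90, 0.04, 1.3) + c(1, -1, 0.5, -0.5, 0, 1, -1)
  base <- fit_sigmoid(conc, y)
  for (a in c(0.1, 10, 250)) {
    scaled <- fit_sigmoid(conc * a, y)
    expect_equal(scaled$ec50, base$ec50 * a, tolerance = 1e-4)
    expect_equal(scaled$hill, base$hill, tolerance = 1e-4)
    expect_equal(scaled$top, base$top, tolerance = 1e-6)
    expect_equal(scaled$bottom, base$bottom, tolerance = 1e-6)
  }
})

test_that("classify_validated applies the dual criterion per dilution", {
  band <- make_band(3000)
  # plateau series peaking at 68.6% at 0.056 mg/mL, non-cytotoxic there
  pts <- data.frame(
    concentration = serial_dilution(0.5, 3, 7)$concentrations,
    activity = c(NA, NA, 68.6, 42.5, 20, 8, 2),
    cell_count = c(800L, 1000L, 4000L, 4100L, 3900L, 4000L, 4050L)
  )
  call <- classify_validated(pts, band, 40)
  expect_true(call$is_active)
  expect_equal(call$best_activity, 68.6)
  expect_equal(call$best_concentration, 0.5 / 9, tolerance = 1e-12)
  # all activities at or below threshold -> inactive
  pts$activity <- c(NA, NA, 40, 35, 20, 8, 2)
  expect_false(classify_validated(pts, band, 40)$is_active)
  # the sole supra-threshold point is cytotoxic -> inactive
  pts$activity <- c(90, NA, 30, 20, 10, 5, 2)
  expect_false(classify_validated(pts, band, 40)$is_active)
  # empty input
  expect_false(classify_validated(pts[0, ], band, 40)$is_active)
})

test_that("classify_validated is order-invariant and breaks ties toward potency", {
  band <- make_band(3000)
  pts <- data.frame(
    concentration = c(0.5, 0.167, 0.056, 0.0185),
    activity = c(50, 61, 61, 45),
    cell_count = rep(4000L, 4)
  )
  base <- classify_validated(pts, band, 40)
  expect_equal(base$best_concentration, 0.056) # tie at 61 -> lower concentration
  for (perm in list(4:1, c(2, 4, 1, 3))) {
    expect_equal(classify_validated(pts[perm, ], band, 40), base)
  }
})

test_that("activity_vs_cellnumber emits a tidy ordered diagnostic table", {
  expect_equal(nrow(activity_vs_cellnumber(NULL)), 0)
  conc <- serial_dilution(0.5, 3, 7)$concentrations
  pts <- simulate_dose_series(
    list(bottom = 0, top = 70, ec50 = 0.02, hill = 1.5), conc,
    noise_sd = 0, cytotoxic_above = 0.2, seed = 3,
    cells_mean = 3500, cells_sd = 100 # healthy wells stay well above the floor
  )
  band <- make_band(3000)
  tab <- activity_vs_cellnumber(pts, band)
  expect_equal(nrow(tab), 7)
  expect_true(all(diff(tab$concentration) < 0))
  # cytotoxic dilutions keep their cell count but have missing activity
  tox <- tab$concentration > 0.2
  expect_true(all(is.na(tab$activity[tox])))
  expect_true(all(tab$cell_count[tox] > 0))
  expect_identical(tab$cytotoxic_flag, tab$cell_count < band$floor)
  expect_identical(tab$cytotoxic_flag, tox)
})
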