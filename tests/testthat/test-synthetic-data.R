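# Generators: planted ground truth, seed determinism, zero-noise
# round-trip behaviour.

test_that("simulate_screen lays out the library with planted truth", {
  sim <- simulate_screen(screen_scenario(
    n_extracts = 480, n_true_hits = 7, hit_effect = c(47, 68),
    n_cytotoxic = 20, seed = 1
  ))
  ext <- sim$measurements[sim$measurements$role == "EXTRACT", ]
  expect_equal(nrow(ext), 480)
  expect_equal(sum(sim$ground_truth$is_hit), 7)
  expect_equal(sum(sim$ground_truth$is_cytotoxic), 20)
  expect_setequal(unique(sim$measurements$role), c("NEG", "POS", "EXTRACT"))
  # planted-count conservation: hit truth matches wells given the hit effect
  hit_ids <- sim$ground_truth$extract_id[sim$ground_truth$is_hit]
  expect_true(all(sim$ground_truth$true_activity[sim$ground_truth$is_hit] > 40))
  expect_true(all(sim$ground_truth$true_activity[match(hit_ids, sim$ground_truth$extract_id)] >= 47 - 1e-9))
  # controls occupy columns 1 and 12 on every plate
  pm <- sim$plate_map
  expect_true(all(substring(pm$well[pm$role == "NEG"], 2) == "1"))
  expect_true(all(substring(pm$well[pm$role == "POS"], 2) == "12"))
})

test_that("empty library gives a control-only plate and empty truth", {
  sim <- simulate_screen(screen_scenario(
    n_extracts = 0, n_true_hits = 0, n_cytotoxic = 0, seed = 1
  ))
  expect_equal(nrow(sim$ground_truth), 0)
  expect_setequal(unique(sim$measurements$role), c("NEG", "POS", "EMPTY"))
  expect_equal(sum(sim$measurements$role == "NEG"), 8)
  expect_equal(sum(sim$measurements$role == "POS"), 8)
})

test_that("null library has mean percent activity ~ 0 (Monte-Carlo)", {
  # Oracle: with hit_effect absent and null activity centred at 0, the
  # population mean of control-anchored percent activity is 0; the MC mean
  # over 1e4 wells has SE ~ 0.1 activity points.
  sc <- screen_scenario(
    n_extracts = 10000, n_true_hits = 0, n_cytotoxic = 0,
    null_activity_sd = 0, seed = 11
  )
  sim <- simulate_screen(sc)
  ext <- sim$measurements[sim$measurements$role == "EXTRACT", ]
  pa <- 100 * (ext$avg_gfp - sc$neg_mean) / (sc$pos_mean - sc$neg_mean)
  expect_lt(abs(mean(pa)), 0.5)
})

test_that("simulate_screen is bit-identical under the same seed", {
  sc <- screen_scenario(n_extracts = 160, n_true_hits = 3, n_cytotoxic = 5, seed = 99)
  expect_identical(simulate_screen(sc), simulate_screen(sc))
  sc2 <- sc
  sc2$seed <- 100L
  expect_false(identical(simulate_screen(sc), simulate_screen(sc2)))
})

test_that("cytotoxic decoys lose cells and can fall below the reporting floor", {
  sc <- screen_scenario(
    n_extracts = 80, n_true_hits = 0, n_cytotoxic = 10,
    cytotoxic_kill_fraction = 0.9, seed = 5
  )
  sim <- simulate_screen(sc)
  tox_ids <- sim$ground_truth$extract_id[sim$ground_truth$is_cytotoxic]
  meas <- sim$measurements
  tox <- meas[!is.na(meas$extract_id) & meas$extract_id %in% tox_ids, ]
  ok <- meas[meas$role == "EXTRACT" & !(meas$extract_id %in% tox_ids), ]
  expect_true(all(tox$cell_count < sc$missing_gfp_floor * sc$cells_per_well_mean))
  expect_true(all(tox$gfp_missing))
  expect_true(all(is.na(tox$avg_gfp)))
  expect_true(mean(ok$cell_count) > 5 * mean(tox$cell_count))
})

test_that("scenario validation and layout errors are raised", {
  expect_error(screen_scenario(n_extracts = 5, n_true_hits = 4, n_cytotoxic = 2), class = "hcs_domain_error")
  expect_error(screen_scenario(pos_mean = 100, neg_mean = 200), class = "hcs_domain_error")
  expect_error(screen_scenario(hit_effect = 30), class = "hcs_domain_error")
  expect_error(
    simulate_screen(screen_scenario(seed = 1), neg_col = 3, pos_col = 3),
    class = "hcs_layout_error"
  )
})

test_that("simulate_dose_series follows the 4PL exactly at zero noise", {
  fit <- list(bottom = 0, top = 100, ec50 = 0.05, hill = 1)
  # midpoint at the EC50
  s <- simulate_dose_series(fit, c(0.05), noise_sd = 0, seed = 1)
  expect_equal(s$activity, 50)
  # low-concentration limit approaches bottom
  s <- simulate_dose_series(fit, c(1e-12), noise_sd = 0, seed = 1)
  expect_equal(s$activity, 0, tolerance = 1e-6)
  # a plateau planted at 68.6% is emitted as 68.6 at that dilution
  conc <- serial_dilution(0.5, 3, 7)$concentrations
  plateau <- list(bottom = 0, top = 68.6, ec50 = 1e-4, hill = 2)
  s <- simulate_dose_series(plateau, conc, noise_sd = 0, seed = 1)
  expect_equal(
    s$activity[abs(s$concentration - 0.056) < 1e-3],
    logistic4(conc[3], 0, 68.6, 1e-4, 2),
    tolerance = 1e-12
  )
  expect_equal(s$activity[3], 68.6, tolerance = 0.1)
})

test_that("dose series flags cytotoxic dilutions and validates inputs", {
  fit <- list(bottom = 0, top = 100, ec50 = 0.05, hill = 1)
  conc <- serial_dilution(0.5, 3, 7)$concentrations
  s <- simulate_dose_series(fit, conc, noise_sd = 0, cytotoxic_above = 0.2, seed = 2)
  expect_identical(s$cytotoxic_true, conc > 0.2)
  expect_true(all(is.na(s$activity[s$cytotoxic_true])))
  expect_true(all(!is.na(s$activity[!s$cytotoxic_true])))
  expect_lt(mean(s$cell_count[s$cytotoxic_true]), min(s$cell_count[!s$cytotoxic_true]))
  expect_error(simulate_dose_series(fit, c(0.5, -0.1), 0), class = "hcs_domain_error")
  expect_error(simulate_dose_series(fit, c(0.1, 0.5), 0), class = "hcs_domain_error")
})

test_that("simulate_flow matches its moments and rejects bad sizes", {
  expect_equal(simulate_flow(10, mean = 7, sd = 0, seed = 1), rep(7, 10))
  x <- simulate_flow(1e5, mean = 100, sd = 10, seed = 4)
  expect_length(x, 1e5)
  expect_lt(abs(mean(x) - 100), 0.2) # CLT bound 3*sd/sqrt(n) ~ 0.095
  expect_error(simulate_flow(0, 100, 10), class = "hcs_domain_error")
})

test_that("simulate_qpcr plants the exact delta-delta-Ct", {
  # true_rq = 1: all delta-Ct equal
  ct <- simulate_qpcr(1, seed = 1)
  expect_equal(ct$ct_target_treated - ct$ct_hk_treated, ct$ct_target_ref - ct$ct_hk_ref)
  # true_rq = 2 -> ddCt = -1
  ct <- simulate_qpcr(2, seed = 1)
  ddct <- (ct$ct_target_treated - ct$ct_hk_treated) - (ct$ct_target_ref - ct$ct_hk_ref)
  expect_equal(ddct, -1)
  expect_error(simulate_qpcr(0), class = "hcs_domain_error")
  expect_error(simulate_qpcr(-2), class = "hcs_domain_error")
})

test_that("zero-noise round trips recover planted parameters exactly", {
  # qPCR -> RQ estimator for a range of planted fold changes
  for (rq in c(0.25, 1, 2.93, 9.48, 100)) {
    ct <- simulate_qpcr(rq, seed = 3)
    est <- rq_ddct(ct$ct_target_treated, ct$ct_hk_treated, ct$ct_target_ref, ct$ct_hk_ref)
    expect_equal(est$rq, rq, tolerance = 1e-12)
  }
  # flow -> MFI at sd = 0
  expect_equal(mfi(simulate_flow(50, 123.4, 0, seed = 1)), 123.4)
})
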