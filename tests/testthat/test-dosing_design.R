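test_that("the AUC-target dose equation and its inverse hold", {
  expect_equal(daily_dose_for_target(0.309), 123.6)
  expect_equal(daily_dose_for_target(1), 400)
  for (cl in c(0.1, 0.309, 0.7, 2)) {
    expect_equal(steady_state_auc24(daily_dose_for_target(cl), cl), 400)
  }
  expect_equal(daily_dose_for_target(0.5, target = 400, mic = 2), 400)
  expect_error(daily_dose_for_target(0), "positive")
})

test_that("the growth lookup is monotone and maps PMA into the weight bands", {
  expect_equal(pma_to_weight(36), 2.80) # lookup node
  grid <- seq(28, 44, by = 0.5)
  expect_true(all(diff(pma_to_weight(grid)) >= 0))
  # published band pairing, e.g. PMA 35-38 wk -> 2.5-3.49 kg
  expect_true(all(pma_to_weight(35:38) >= 2.5 & pma_to_weight(35:38) < 3.5))
  expect_true(all(pma_to_weight(28:30) >= 1.0 & pma_to_weight(28:30) < 1.5))
  expect_true(all(pma_to_weight(31:34) >= 1.5 & pma_to_weight(31:34) < 2.5))
  expect_true(all(pma_to_weight(39:42) >= 3.5 & pma_to_weight(39:42) < 4.5))
  expect_true(all(pma_to_weight(43:44) >= 4.5 & pma_to_weight(43:44) <= 5.5))
  expect_error(pma_to_weight(60), "range")
})

test_that("scenario grids cover PMA 28-44 and validate inputs", {
  sc <- dosing_scenarios()
  expect_equal(sort(unique(sc$PMA)), seq(28, 44, by = 2))
  expect_equal(sort(unique(sc$SCR)), c(10, 25, 45, 60))
  expect_error(dosing_scenarios(pma = 50), "28")
  expect_warning(dosing_scenarios(scr = 80), "extrapolating")
  # alternate creatinine grids are supported
  expect_equal(unique(dosing_scenarios(scr = c(15, 35))$SCR), c(15, 35))
})

test_that("Monte Carlo AUC sampling behaves at the degenerate and seeded cases", {
  sc <- data.frame(WT = 3.0, SCR = 25)
  cl_typ <- typical_clearance(3.0, 25)
  # omega = 0: every sample equals the typical AUC24
  a0 <- simulate_auc_distribution(sc, daily_dose = 120, omega2 = 0, n = 50)
  expect_true(all(a0 == 120 / cl_typ))
  # dosing exactly at the target puts the median near 400
  dd <- daily_dose_for_target(cl_typ)
  a1 <- simulate_auc_distribution(sc, dd, n = 4000, seed = 3)
  expect_lt(abs(median(a1) - 400) / 400, 0.05)
  a2 <- simulate_auc_distribution(sc, dd, n = 100, seed = 9)
  a3 <- simulate_auc_distribution(sc, dd, n = 100, seed = 9)
  expect_identical(a2, a3)
})

test_that("dose-table construction meets the published 3-kg worked example", {
  # deterministic check: the required typical per-dose amount for a 3.0-kg
  # neonate with Scr 25 on q8h falls inside the published 12.5-15 mg/kg
  cl <- typical_clearance(3.0, 25)
  per_dose <- daily_dose_for_target(cl) / 3 / 3.0
  expect_gte(per_dose, 12.5)
  expect_lte(per_dose, 15)
  # table construction: coverage is maximal on the grid and creatinine
  # monotonicity carries through to the recommended daily dose
  sc <- dosing_scenarios(pma = 36, scr = c(10, 25, 45, 60))
  tab <- build_dose_table(sc, n = 400, seed = 11)
  expect_true(all(tab$coverage > 0.5))
  expect_true(all(diff(tab$daily_mgkg) <= 0))
  expect_true(all(tab$dose_mgkg %% 2.5 == 0))
  expect_true(all(tab$q15_daily_mgkg <= tab$q85_daily_mgkg))
  # restricting the dose grid to one entry returns that entry
  tab1 <- build_dose_table(dosing_scenarios(pma = 36, scr = 25),
                           dose_grid = 12.5, intervals = 8, n = 200,
                           seed = 13)
  expect_equal(tab1$dose_mgkg, 12.5)
  expect_equal(tab1$interval_h, 8)
  # pure function of its inputs
  tab2 <- build_dose_table(sc, n = 400, seed = 11)
  expect_identical(tab, tab2)
})

test_that("widening the AUC window never lowers coverage", {
  sc <- dosing_scenarios(pma = 32, scr = 25)
  narrow <- build_dose_table(sc, n = 500, seed = 17, target = 400,
                             upper = 700)
  wide <- build_dose_table(sc, n = 500, seed = 17, target = 400,
                           upper = 900)
  expect_gte(wide$coverage, narrow$coverage)
})

test_that("guideline comparison covers all seven references and classifies directions", {
  gl <- load_guidelines()
  expect_length(gl, 7)
  tab <- build_dose_table(n = 500, seed = 19)
  cmp <- compare_to_guidelines(tab, gl)
  expect_equal(length(unique(cmp$guideline)), 7)
  expect_true(all(cmp$classification %in%
                    c("below", "within", "above", "not_covered")))
  # a synthetic guideline equal to the model mean is always 'within'
  fake <- list(list(name = "model-mean", rules = data.frame(
    pma_min = NA, pma_max = NA, pna_min = NA, pna_max = NA, ga_min = NA,
    ga_max = NA, wt_min = NA, wt_max = NA, scr_min = NA, scr_max = NA,
    dose_lo = NA, dose_hi = NA, interval_lo = 24, interval_hi = 24)))
  for (i in seq_len(nrow(tab))) {
    fake[[1]]$rules$dose_lo <- tab$mean_required_daily_mgkg[i]
    fake[[1]]$rules$dose_hi <- tab$mean_required_daily_mgkg[i]
    one <- compare_to_guidelines(tab[i, ], fake)
    expect_equal(one$classification, "within")
  }
  # the flat 10 mg/kg label under-doses the high-clearance (Scr 10)
  # scenarios: classified below for most of them
  fda <- cmp[cmp$guideline == "FDA labeled dosage (2017)" & cmp$SCR == 10, ]
  expect_gt(mean(fda$classification == "below"), 0.5)
})
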