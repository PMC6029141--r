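test_that("final-model typical values reproduce the published worked examples", {
  th <- fixed_effects()
  expect_equal(typical_clearance(2.9, 23.3, th), 0.309, tolerance = 1e-12)
  expect_equal(typical_volume(2.9, th), 2.63, tolerance = 1e-12)
  # forced by the functional form: doubling Scr or WT scales by 2^exponent
  expect_equal(typical_clearance(2.9, 46.6, th), 0.309 * 2^-0.337)
  expect_equal(typical_clearance(5.8, 23.3, th), 0.309 * 2^1.55)
  expect_equal(typical_volume(5.8, th), 2.63 * 2^1.05)
  expect_equal(typical_volume(2.9, fixed_effects(v_wt_exponent = 0)), 2.63)
  expect_error(typical_clearance(-1, 20), "positive")
  expect_error(typical_volume(0), "positive")
})

test_that("individual parameters apply eta to clearance only", {
  p0 <- individual_params(eta = 0, wt = 2.9, scr = 23.3)
  expect_equal(p0$CL, 0.309)
  expect_equal(p0$V, 2.63)
  expect_equal(p0$ke, 0.309 / 2.63)
  p2 <- individual_params(eta = log(2), wt = 2.9, scr = 23.3)
  expect_equal(p2$CL, 2 * p0$CL)
  expect_equal(p2$V, p0$V)
})

test_that("covariate factor identities hold", {
  # centering: COV at its median gives factor 1 for any exponent
  for (th in c(-1, 0.5, 2)) {
    sp <- cov_power("WT", ref = 2.9, theta = th)
    expect_equal(covariate_factor(sp, 2.9), 1)
  }
  # inverted ratio (creatinine orientation)
  spi <- cov_power("SCR", ref = 23.3, theta = 0.337, invert = TRUE)
  expect_equal(covariate_factor(spi, 46.6), (23.3 / 46.6)^0.337)
  # sigmoid midpoint: maturation factor is 0.5 at TM50 in both orientations
  for (pf in c(FALSE, TRUE)) {
    spm <- cov_maturation("WT", age_cov = "PMA", ref = 2.9, tm50 = 40,
                          hill = 3.2, printed_form = pf)
    expect_equal(covariate_factor(spm, list(WT = 2.9, PMA = 40)), 0.5)
  }
  # conventional orientation rises with age, printed form falls
  spc <- cov_maturation("WT", age_cov = "PMA", ref = 2.9, tm50 = 40, hill = 3)
  young <- covariate_factor(spc, list(WT = 2.9, PMA = 30))
  old <- covariate_factor(spc, list(WT = 2.9, PMA = 50))
  expect_true(young < 0.5 && old > 0.5)
  spp <- cov_maturation("WT", age_cov = "PMA", ref = 2.9, tm50 = 40, hill = 3,
                        printed_form = TRUE)
  expect_true(covariate_factor(spp, list(WT = 2.9, PMA = 30)) > 0.5)
  # nesting: kmax = 0 collapses the varying-exponent models to the simple
  # power model with theta = theta0
  wts <- c(1.5, 2.9, 5.5)
  sp3 <- cov_wde("WT", ref = 2.9, theta0 = 1.3, kmax = 0, k50 = 3, hill = 2)
  sp1 <- cov_power("WT", ref = 2.9, theta = 1.3)
  expect_equal(covariate_factor(sp3, wts), covariate_factor(sp1, wts))
  sp4 <- cov_ade("WT", age_cov = "PMA", ref = 2.9, theta0 = 1.3, kmax = 0,
                 k50 = 40, hill = 2)
  expect_equal(covariate_factor(sp4, list(WT = wts, PMA = c(30, 35, 44))),
               covariate_factor(sp1, wts))
  # time-varying baseline/delta collapses to no effect at zero thetas
  sptv <- cov_tv_baseline_delta("SCR", ref = 23, theta_bcov = 0,
                                theta_dcov = 0)
  expect_equal(covariate_factor(sptv, list(SCR = c(10, 40), BSCR = c(20, 20))),
               c(1, 1))
  # categorical: reference level 1, other level theta
  spk <- cov_categorical("SEX", ref_level = 0, frac = 0.8)
  expect_equal(covariate_factor(spk, c(0, 1, 0)), c(1, 0.8, 1))
  expect_error(covariate_factor(cov_power("WT", ref = 2.9), -1), "positive")
})

test_that("closed-form infusion predictions match the ODE oracle", {
  params <- list(CL = 0.42, V = 3.1)
  doses <- data.frame(start = seq(0, 32, by = 8), amount = 38, duration = 2)
  probes <- sort(runif(50, 0.2, 44))
  set.seed(99)
  closed <- predict_concentration(params, doses, probes)
  ode <- ode_concentration(params, doses, probes)
  expect_equal(closed, ode, tolerance = 1e-6)
  # t = 0 and pre-dose times predict zero
  expect_equal(predict_concentration(params, doses, 0), 0)
  late <- data.frame(start = 10, amount = 40, duration = 2)
  expect_equal(predict_concentration(params, late, c(0, 5, 10)), c(0, 0, 0))
})

test_that("steady-state and superposition identities hold", {
  params <- list(CL = 0.5, V = 2.8)
  ke <- params$CL / params$V
  # a never-ending infusion approaches R0/CL
  long <- data.frame(start = 0, amount = 1000 * 5, duration = 1000)
  t_inf <- 20 / ke
  expect_equal(predict_concentration(params, long, t_inf), 5 / params$CL,
               tolerance = 1e-6)
  # doubling every dose doubles every prediction (linearity)
  doses <- data.frame(start = c(0, 8, 16, 24, 32), amount = 35, duration = 2)
  doses2 <- transform(doses, amount = 2 * amount)
  times <- c(3, 10, 20, 33, 35, 39.5)
  expect_equal(predict_concentration(params, doses2, times),
               2 * predict_concentration(params, doses, times))
  # shifting all times leaves predictions unchanged
  shift <- 13
  expect_equal(
    predict_concentration(params, transform(doses, start = start + shift),
                          times + shift),
    predict_concentration(params, doses, times))
  # clearance monotonicity of the covariate model
  th <- fixed_effects()
  wt <- seq(1.5, 5.5, by = 0.5)
  expect_true(all(diff(typical_clearance(wt, 23.3, th)) > 0))
  scr <- seq(6, 60, by = 6)
  expect_true(all(diff(typical_clearance(2.9, scr, th)) < 0))
})

test_that("steady-state AUC24 equals daily dose over clearance", {
  expect_equal(steady_state_auc24(400 * 0.7, 0.7), 400)
  expect_equal(steady_state_auc24(123.6, 0.309), 400)
  expect_error(steady_state_auc24(100, 0), "positive")
  # numerical check: integrate the steady-state profile over one day
  params <- list(CL = 0.35, V = 2.9)
  per_dose <- 40
  doses <- data.frame(start = seq(0, 24 * 14, by = 8), amount = per_dose,
                      duration = 2)
  grid <- seq(24 * 12, 24 * 13, length.out = 4001)
  conc <- predict_concentration(params, doses, grid)
  auc_num <- sum(diff(grid) * (head(conc, -1) + conc[-1]) / 2)
  expect_equal(auc_num, steady_state_auc24(per_dose * 3, params$CL),
               tolerance = 1e-3)
})
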