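# The quadrature oracle is checked against brute-force trapezoid
# integration, and FOCE-I is checked against the quadrature oracle.

final_start <- function() {
  final_model_spec(theta = fixed_effects(
    cl_typical = 0.3, cl_wt_exponent = 1.3, cl_scr_exponent = 0.3,
    v_typical = 2.5, v_wt_exponent = 1.0), iiv_cv = 30, sigma_prop = 0.3)
}

test_that("omega = 0 collapses FOCE and quadrature to extended least squares", {
  ds <- make_tiny_dataset(n = 3, seed = 11)
  spec <- final_model_spec(iiv_cv = 0)
  spec$iiv$omega2 <- 0
  fo <- foce_objective(ds, spec)
  qo <- exact_objective_quadrature(ds, spec, nodes = 32)
  expect_equal(fo$ofv, qo$ofv, tolerance = 1e-10)
  # equals the fixed-effects ELS objective computed directly
  fl <- neovanc:::flatten_dataset(ds)
  tv <- neovanc:::eval_typicals(spec, fl$covs)
  els <- 0
  for (j in seq_len(fl$n_obs)) {
    i <- findInterval(j - 1, fl$obs_off[-length(fl$obs_off)])
    d <- seq(fl$dose_off[i] + 1, fl$dose_off[i + 1])
    doses <- data.frame(start = fl$dose_start[d],
                        amount = fl$dose_rate[d] * fl$dose_dur[d],
                        duration = fl$dose_dur[d])
    f <- predict_concentration(list(CL = tv$cl[j], V = tv$v[j]), doses,
                               fl$obs_time[j])
    v <- spec$residual$prop^2 * f^2
    els <- els + (fl$dv[j] - f)^2 / v + log(v)
  }
  expect_equal(fo$ofv, els, tolerance = 1e-8)
})

test_that("adaptive quadrature matches brute-force integration per subject", {
  ds <- make_tiny_dataset(n = 3, seed = 13)
  spec <- final_model_spec(iiv_cv = 35, sigma_prop = 0.3)
  qo <- exact_objective_quadrature(ds, spec, nodes = 64)
  fl <- neovanc:::flatten_dataset(ds)
  tv <- neovanc:::eval_typicals(spec, fl$covs)
  for (i in 1:3) {
    o <- seq(fl$obs_off[i] + 1, fl$obs_off[i + 1])
    d <- seq(fl$dose_off[i] + 1, fl$dose_off[i + 1])
    doses <- data.frame(start = fl$dose_start[d],
                        amount = fl$dose_rate[d] * fl$dose_dur[d],
                        duration = fl$dose_dur[d])
    ref <- trapezoid_neg2ll(fl$dv[o], fl$obs_time[o], tv$cl[o], tv$v[o],
                            doses, spec$iiv$omega2, spec$residual$prop^2,
                            0) - length(o) * log(2 * pi)
    expect_equal(unname(qo$contributions[i]), ref, tolerance = 1e-7)
  }
  # node-doubling convergence, measured on an additive-error cohort whose
  # integrand is closest to Gaussian (the proportional-error integrand
  # converges more slowly, ~1e-5 at 32 nodes)
  spec_add <- model_spec(
    cl = 0.31, v = 2.6,
    cl_covs = list(cov_power("WT", ref = 2.9, theta = 1.55),
                   cov_power("SCR", ref = 23.3, theta = 0.337,
                             invert = TRUE)),
    v_covs = list(cov_power("WT", "V", ref = 2.9, theta = 1.05)),
    residual = residual_spec("additive", add = 1.5),
    iiv = iiv_spec(cv = 35))
  q32 <- exact_objective_quadrature(ds, spec_add, nodes = 32)
  q64 <- exact_objective_quadrature(ds, spec_add, nodes = 64)
  expect_lt(abs(q64$ofv - q32$ofv), 1e-7)
  expect_error(exact_objective_quadrature(ds, spec, nodes = 8), ">= 16")
})

test_that("FOCE-I approximation tracks the exact objective", {
  # near-degenerate variability: the linearization error is O(omega^2) and
  # essentially vanishes (measured ~3e-5 per subject at CV 0.1%)
  sim <- simulate_cohort(cohort_config(n_subjects = 10, seed = 31,
                                       iiv_cv = 0.1, sigma_cv = 10))
  spec <- final_model_spec(iiv_cv = 0.1, sigma_prop = 0.1)
  fo <- foce_objective(sim$dataset, spec)
  qo <- exact_objective_quadrature(sim$dataset, spec, nodes = 64)
  expect_lt(abs(fo$ofv - qo$ofv) / 10, 1e-4)
  # at study-level variability agreement stays within 0.5 per subject
  sim2 <- simulate_cohort(cohort_config(n_subjects = 40, seed = 37))
  fo2 <- foce_objective(sim2$dataset, final_model_spec())
  qo2 <- exact_objective_quadrature(sim2$dataset, final_model_spec(),
                                    nodes = 64)
  expect_lt(abs(fo2$ofv - qo2$ofv) / 40, 0.5)
})

test_that("objective is invariant to subject order", {
  sim <- simulate_cohort(cohort_config(n_subjects = 8, seed = 41))
  ds <- sim$dataset
  perm <- ds
  perm$subjects <- perm$subjects[c(5, 2, 8, 1, 7, 3, 6, 4)]
  spec <- final_model_spec()
  expect_equal(foce_objective(ds, spec)$ofv,
               foce_objective(perm, spec)$ofv, tolerance = 1e-10)
})

test_that("noise-free data recover the generating parameters", {
  sim <- simulate_cohort(cohort_config(n_subjects = 40, seed = 43,
                                       iiv_cv = 0, sigma_cv = 1))
  spec <- final_start()
  spec$iiv <- iiv_spec(omega2 = 0, estimate = FALSE)
  spec$residual <- residual_spec("proportional", prop = 0.05)
  f <- fit(sim$dataset, spec, fit_config(compute_se = FALSE))
  est <- setNames(f$parameters$estimate, f$parameters$name)
  truth <- c(CL.pop = 0.309, V.pop = 2.63, CL.WT.theta = 1.55,
             CL.SCR.theta = 0.337, V.WT.theta = 1.05)
  expect_true(all(abs(est[names(truth)] - truth) / truth < 0.01))
})

test_that("fit reports consistent information criteria and structure", {
  sim <- simulate_cohort(cohort_config(n_subjects = 30, seed = 47))
  f <- fit(sim$dataset, final_start(), fit_config(compute_se = TRUE))
  expect_equal(f$aic, f$ofv + 2 * f$n_par)
  expect_equal(f$bic, f$ofv + f$n_par * log(f$n_obs))
  expect_equal(f$ofv_with_constant, f$ofv + f$n_obs * log(2 * pi))
  expect_equal(f$ofv, sum(f$contributions), tolerance = 1e-8)
  expect_gte(f$condition_number, 1)
  expect_equal(nrow(f$diagnostics), 60)
  expect_true(f$converged)
  # warm start at the optimum returns (at least) the same objective
  f2 <- fit(sim$dataset, final_start(), fit_config(compute_se = FALSE),
            start = f$opt_par)
  expect_lte(f2$ofv, f$ofv + 1e-6)
})

test_that("CWRES has the advertised degenerate form and flags gross outliers", {
  # omega = 0 with additive error: CWRES = (DV - PRED) / sigma exactly
  ds <- make_tiny_dataset(n = 3, seed = 53)
  spec <- model_spec(cl = 0.31, v = 2.6,
                     cl_covs = list(cov_power("WT", ref = 2.9, theta = 1.55),
                                    cov_power("SCR", ref = 23.3, theta = 0.337,
                                              invert = TRUE)),
                     v_covs = list(cov_power("WT", "V", ref = 2.9,
                                             theta = 1.05)),
                     residual = residual_spec("additive", add = 2),
                     iiv = iiv_spec(omega2 = 0))
  ev <- evaluate_model(ds, spec)
  expect_equal(ev$diagnostics$cwres,
               (ev$diagnostics$dv - ev$diagnostics$pred) / 2,
               tolerance = 1e-10)
  # calibration under the generating model
  sim <- simulate_cohort(cohort_config(n_subjects = 80, seed = 59))
  f <- fit(sim$dataset, final_start(), fit_config(compute_se = FALSE))
  cw <- f$diagnostics$cwres
  expect_lt(abs(mean(cw)), 0.1)
  expect_lt(abs(var(cw) - 1), 0.35)
  # a 10x perturbed observation is flagged by the +/-6 screen (perturb a
  # full-sized peak: with proportional error a 10x shift of a tiny trough
  # can legitimately hide inside the conditional variance)
  ds2 <- sim$dataset
  k <- which.max(vapply(ds2$subjects,
                        function(s) max(s$observations$value), 0))
  j <- which.max(ds2$subjects[[k]]$observations$value)
  ds2$subjects[[k]]$observations$value[j] <-
    10 * ds2$subjects[[k]]$observations$value[j]
  ev2 <- evaluate_model(ds2, f$spec)
  bad <- ev2$diagnostics$id == ds2$subjects[[k]]$id
  expect_gt(max(abs(ev2$diagnostics$cwres[bad])), 6)
})
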