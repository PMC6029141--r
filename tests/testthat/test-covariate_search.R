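# The heavy selection-consistency and type-I calibration experiments live
# in test-acceptance.R; these tests pin the mechanics and contracts on a
# single shared cohort (fits are computed once at file level).

sc_ds <- simulate_cohort(cohort_config(n_subjects = 50, seed = 203))$dataset
sc_med <- neovanc:::dataset_medians(sc_ds)
sc_cfg <- search_config(estimation = fit_config(restarts = 1, maxit = 800, reltol = 1e-8))
sc_s1 <- step1_size_models(sc_ds, sc_cfg)
sc_s2 <- step2_renal_models(sc_ds, sc_s1, sc_cfg)
sc_fast <- fit_config(compute_se = FALSE, restarts = 1, maxit = 800, reltol = 1e-8)

test_that("step 1 reports exactly four clearance candidates and picks a winner", {
  expect_equal(nrow(sc_s1$table), 4)
  expect_true(grepl("^I", sc_s1$table$model[1]))
  expect_true(sc_s1$best %in% sc_s1$table$model)
  expect_true(sc_s1$table$stable[sc_s1$table$model == sc_s1$best])
  stable_aic <- ifelse(sc_s1$table$stable, sc_s1$table$aic, Inf)
  expect_equal(sc_s1$best, sc_s1$table$model[which.min(stable_aic)])
})

test_that("the WT-dependent exponent model nests the simple exponent model", {
  vc <- list(cov_power("WT", "V", ref = sc_med[["WT"]], theta = 1))
  spI <- model_spec(cl = 0.3, v = 2.6,
                    cl_covs = list(cov_power("WT", ref = sc_med[["WT"]],
                                             theta = 1)), v_covs = vc)
  fI <- fit(sc_ds, spI, sc_fast)
  cw <- cov_wde("WT", ref = sc_med[["WT"]], theta0 = 1, kmax = 0, k50 = 3,
                hill = 3, estimate = c(theta0 = TRUE))
  spIII <- model_spec(cl = 0.3, v = 2.6, cl_covs = list(cw), v_covs = vc)
  fIII <- fit(sc_ds, spIII, sc_fast)
  expect_lt(abs(fI$ofv - fIII$ofv), 0.1)
})

test_that("step 2 keeps the better renal form and records both OFV drops", {
  expect_equal(sc_s2$table$model, c("Scr power", "Scr linear"))
  expect_true(all(c("ofv", "dofv") %in% names(sc_s2$table)))
  expect_true(sc_s2$included)
  expect_true("SCR" %in% cl_cov_names(sc_s2$spec))
  # nested-model monotonicity: the richer model cannot fit worse
  expect_true(all(sc_s2$table$dofv > -0.1, na.rm = TRUE))
  # the kept form is the one with the lower OFV
  expect_equal(sc_s2$fit$ofv, min(sc_s2$table$ofv, na.rm = TRUE),
               tolerance = 1e-9)
})

test_that("forward/backward mechanics behave on contract cases", {
  # empty candidate set leaves the model unchanged
  s3 <- step3_forward_backward(sc_ds, sc_s2$fit, candidates = list(),
                               config = sc_cfg)
  expect_equal(s3$fit$ofv, sc_s2$fit$ofv)
  expect_length(s3$added, 0)
  # screening an irrelevant covariate yields a small, recorded OFV drop
  scr <- screen_candidates(sc_ds, sc_s2$fit,
                           list(ALB = cov_power("ALB", ref = sc_med[["ALB"]],
                                                theta = 0)), sc_cfg)
  expect_equal(scr$candidate, "ALB")
  expect_true(is.finite(scr$dofv))
  expect_gt(scr$dofv, -0.1)
  # an exact tie is broken deterministically by candidate list order
  cands <- list(A = cov_power("ALB", ref = sc_med[["ALB"]], theta = 0),
                B = cov_power("ALB", ref = sc_med[["ALB"]], theta = 0))
  attr(cands, "group") <- c(A = "g1", B = "g2")
  tie <- screen_candidates(sc_ds, sc_s2$fit, cands, sc_cfg)
  expect_equal(tie$dofv[1], tie$dofv[2], tolerance = 1e-6)
})

test_that("step 4 skips static covariates and nests the static model", {
  s4 <- step4_time_varying(sc_ds, sc_s2$fit, sc_cfg)
  expect_true(any(grepl("skipped", s4$notes)))
  expect_equal(s4$fit$ofv, sc_s2$fit$ofv)
  # inject within-subject creatinine drift so the variants actually fit
  ds2 <- sc_ds
  for (i in seq_along(ds2$subjects)) {
    cv <- ds2$subjects[[i]]$covariates
    cv2 <- cv
    cv2$time <- 30
    cv2$SCR <- cv$SCR * 1.3
    ds2$subjects[[i]]$covariates <- rbind(cv, cv2)
  }
  s4b <- step4_time_varying(ds2, sc_s2$fit, sc_cfg)
  expect_false(is.null(s4b$table))
  expect_true(any(grepl("SCR", s4b$table$model)))
  # per-subject baseline/delta decomposition is recorded
  expect_false(is.null(s4b$decomposition))
  expect_equal(sort(unique(s4b$decomposition$id)),
               sort(vapply(ds2$subjects, function(s) s$id, "")))
  # with the change-from-baseline effect pinned to zero, the
  # baseline/delta decomposition collapses to the static proportional
  # slope model (on static data baseline and current value coincide)
  sp_tv <- neovanc:::add_cl_cov(
    sc_s1$fit$spec,
    cov_tv_baseline_delta("SCR", ref = sc_med[["SCR"]], theta_bcov = 0,
                          theta_dcov = 0,
                          estimate = c(theta_bcov = TRUE,
                                       theta_dcov = FALSE)))
  sp_static <- neovanc:::add_cl_cov(
    sc_s1$fit$spec, cov_tv_random("SCR", ref = sc_med[["SCR"]], slope = 0))
  f_tv <- fit(sc_ds, sp_tv, sc_fast)
  f_static <- fit(sc_ds, sp_static, sc_fast)
  expect_lt(abs(f_static$ofv - f_tv$ofv), 0.1)
})
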