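#' Goodness-of-fit table
#'
#' One row per observation with the observed value, population and
#' individual predictions, CWRES and time after the most recent dose; this
#' long table feeds the standard diagnostic scatterplots (DV vs IPRED, DV
#' vs PRED, CWRES vs time, CWRES vs PRED).
#'
#' @param fit a `vanc_fit`
#' @param dataset the fitted `population_dataset` (for dose times)
#' @return data.frame with columns `id`, `time`, `tad`, `dv`, `pred`,
#'   `ipred`, `cwres`
#' @export
gof_tables <- function(fit, dataset) {
  d <- fit$diagnostics
  dose_starts <- setNames(
    lapply(dataset$subjects, function(s) s$doses$start),
    vapply(dataset$subjects, function(s) as.character(s$id), character(1)))
  tad <- vapply(seq_len(nrow(d)), function(i) {
    st <- dose_starts[[d$id[i]]]
    st <- st[st <= d$time[i]]
    if (length(st) == 0) NA_real_ else d$time[i] - max(st)
  }, numeric(1))
  data.frame(id = d$id, time = d$time, tad = tad, dv = d$dv,
             pred = d$pred, ipred = d$ipred, cwres = d$cwres,
             stringsAsFactors = FALSE)
}

#' Flag CWRES outliers
#'
#' Observations whose conditional weighted residual lies outside
#' `[-bound, bound]`; the study's screening rule uses 6.
#'
#' @param fit a `vanc_fit`
#' @param bound symmetric CWRES bound
#' @return data.frame of flagged observations (empty when none)
#' @export
flag_outliers <- function(fit, bound = 6) {
  d <- fit$diagnostics
  out <- d[abs(d$cwres) > bound, c("id", "time", "dv", "cwres")]
  rownames(out) <- NULL
  out
}

#' Nonparametric bootstrap of a population model
#'
#' Resamples subjects with replacement (keeping the cohort size), refits
#' each resample starting from the original point estimates, and
#' summarizes the parameter distribution by median, 2.5/97.5 percentiles
#' and relative bias versus the point estimate. Non-converged replicates
#' count against the success fraction and are excluded from the
#' percentiles; a success fraction below 50% flags the summary as
#' unreliable.
#'
#' @param dataset the original `population_dataset`
#' @param spec the model to refit (typically `fit$spec`)
#' @param n_resamples number of bootstrap replicates
#' @param seed RNG seed
#' @param point_fit optional original fit; refitted here when absent
#' @param config [fit_config()] for the replicate fits (standard errors
#'   are skipped for speed)
#' @return object of class `bootstrap_summary` with elements `table`
#'   (per-parameter summary), `success_fraction`, `n_resamples`,
#'   `reliable`, `seed`
#' @export
bootstrap <- function(dataset, spec, n_resamples = 200, seed = 1,
                      point_fit = NULL,
                      config = fit_config(compute_se = FALSE)) {
  if (n_resamples < 1) stop_domain("n_resamples must be >= 1")
  if (is.null(point_fit)) point_fit <- fit(dataset, spec, config)
  set.seed(seed)
  n <- length(dataset$subjects)
  draws <- matrix(NA_real_, nrow = n_resamples,
                  ncol = nrow(point_fit$parameters))
  colnames(draws) <- point_fit$parameters$name
  ok <- logical(n_resamples)
  for (b in seq_len(n_resamples)) {
    idx <- sample.int(n, n, replace = TRUE)
    subs <- lapply(seq_along(idx), function(k) {
      s <- dataset$subjects[[idx[k]]]
      s$id <- sprintf("B%04d", k)
      s
    })
    bds <- population_dataset(subs, provenance = list(bootstrap = b))
    f <- tryCatch(suppressWarnings(
      fit(bds, point_fit$spec, config, start = point_fit$opt_par)),
      error = function(e) NULL)
    if (!is.null(f) && f$converged &&
        all(is.finite(f$parameters$estimate))) {
      ok[b] <- TRUE
      draws[b, ] <- f$parameters$estimate
    }
  }
  est <- point_fit$parameters$estimate
  good <- draws[ok, , drop = FALSE]
  tab <- data.frame(
    name = point_fit$parameters$name,
    estimate = est,
    median = apply(good, 2, median),
    q2.5 = apply(good, 2, quantile, probs = 0.025),
    q97.5 = apply(good, 2, quantile, probs = 0.975),
    stringsAsFactors = FALSE)
  tab$bias_pct <- (tab$median - tab$estimate) / tab$estimate * 100
  structure(list(table = tab, success_fraction = mean(ok),
                 n_resamples = n_resamples,
                 reliable = mean(ok) >= 0.5, seed = seed,
                 point_fit = point_fit),
            class = "bootstrap_summary")
}

#' @export
print.bootstrap_summary <- function(x, ...) {
  cat(sprintf("<bootstrap_summary> %d resamples, %.1f%% successful%s\n",
              x$n_resamples, 100 * x$success_fraction,
              if (x$reliable) "" else " (UNRELIABLE)"))
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

# simulate replicate observation vectors under a fitted model at the
# observed design; returns a list of n_obs_i x n_sim matrices per subject
simulate_from_model <- function(dataset, spec, n_sim) {
  fl <- flatten_dataset(dataset)
  tv <- eval_typicals(spec, fl$covs)
  omega2 <- spec$iiv$omega2
  sp <- spec$residual$prop
  sa <- spec$residual$add
  lapply(seq_len(fl$n_subjects), function(i) {
    o <- seq(fl$obs_off[i] + 1, fl$obs_off[i + 1])
    d <- seq(fl$dose_off[i] + 1, fl$dose_off[i + 1])
    eta <- if (omega2 > 0) rnorm(n_sim, 0, sqrt(omega2)) else numeric(n_sim)
    sims <- matrix(NA_real_, length(o), n_sim)
    for (j in seq_along(o)) {
      f <- conc_profile_cpp(tv$cl[o[j]] * exp(eta),
                            rep(tv$v[o[j]], n_sim),
                            fl$obs_time[o[j]],
                            fl$dose_start[d], fl$dose_dur[d],
                            fl$dose_rate[d])
      sims[j, ] <- as.numeric(f)
    }
    noise <- matrix(rnorm(length(sims)), nrow(sims), ncol(sims))
    sims * (1 + sp * noise) +
      if (sa > 0) sa * matrix(rnorm(length(sims)), nrow(sims)) else 0
  })
}

#' Normalized prediction distribution errors
#'
#' Simulates `n_sim` replicates of the dataset under the fitted model at
#' the observed design, decorrelates observed and simulated vectors per
#' subject with the Cholesky factor of the empirical simulation covariance
#' (ridge-regularized with a warning if singular), converts mid-ranks of
#' the decorrelated observations (clipped to the open unit interval) to
#' standard-normal quantiles, and applies the three calibration tests:
#' t-test for mean zero, a chi-squared variance-one test (Fisher), and
#' Shapiro-Wilk normality, combined by Bonferroni.
#'
#' @param dataset the observed `population_dataset`
#' @param fit the fitted `vanc_fit`
#' @param n_sim number of simulation replicates (>= 100)
#' @param seed RNG seed
#' @param alpha global significance level
#' @return object of class `npde_summary`: per-observation `npde`,
#'   p-values `p_mean`, `p_var`, `p_normal`, `p_global`, and the `reject`
#'   decision
#' @export
npde <- function(dataset, fit, n_sim = 1000, seed = 1, alpha = 0.05) {
  if (n_sim < 100) stop_domain("n_sim must be >= 100")
  set.seed(seed)
  sims <- simulate_from_model(dataset, fit$spec, n_sim)
  fl <- flatten_dataset(dataset)
  lo <- 1 / (2 * n_sim)
  npde_all <- numeric(fl$n_obs)
  for (i in seq_len(fl$n_subjects)) {
    o <- seq(fl$obs_off[i] + 1, fl$obs_off[i + 1])
    Y <- sims[[i]]
    y <- fl$dv[o]
    m <- rowMeans(Y)
    V <- cov(t(Y))
    L <- tryCatch(chol(V), error = function(e) {
      warning("singular simulation covariance for subject ", fl$ids[i],
              "; ridge-regularized", call. = FALSE)
      chol(V + diag(1e-8 * max(diag(V), 1), nrow(V)))
    })
    dec_obs <- backsolve(L, y - m, transpose = TRUE)
    dec_sim <- backsolve(L, Y - m, transpose = TRUE)
    pde <- vapply(seq_along(o), function(j) {
      (sum(dec_sim[j, ] < dec_obs[j]) +
         0.5 * sum(dec_sim[j, ] == dec_obs[j])) / n_sim
    }, numeric(1))
    npde_all[o] <- qnorm(pmin(pmax(pde, lo), 1 - lo))
  }
  n <- length(npde_all)
  p_mean <- t.test(npde_all)$p.value
  s2 <- var(npde_all)
  stat <- (n - 1) * s2
  p_var <- 2 * min(pchisq(stat, n - 1), 1 - pchisq(stat, n - 1))
  p_normal <- shapiro.test(npde_all)$p.value
  p_global <- min(1, 3 * min(p_mean, p_var, p_normal))
  structure(list(npde = npde_all, p_mean = p_mean, p_var = p_var,
                 p_normal = p_normal, p_global = p_global,
                 reject = p_global < alpha, n_sim = n_sim, seed = seed),
            class = "npde_summary")
}

#' @export
print.npde_summary <- function(x, ...) {
  cat(sprintf(paste0("<npde_summary> n=%d  mean p=%.3f  var p=%.3f  ",
                     "normality p=%.3f  global p=%.3f (%s)\n"),
              length(x$npde), x$p_mean, x$p_var, x$p_normal, x$p_global,
              if (x$reject) "REJECT" else "no rejection"))
  invisible(x)
}
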