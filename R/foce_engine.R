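#' Estimation settings
#'
#' @param maxit maximum Nelder-Mead iterations per stage
#' @param restarts number of polish restarts from the incumbent optimum
#' @param reltol relative convergence tolerance on the objective
#' @param hess_step relative finite-difference step for the Hessian
#' @param compute_se compute standard errors / condition number?
#' @return a list of class `fit_config`
#' @export
fit_config <- function(maxit = 1500, restarts = 1, reltol = 1e-9,
                       hess_step = 1e-4, compute_se = TRUE) {
  structure(list(maxit = maxit, restarts = restarts, reltol = reltol,
                 hess_step = hess_step, compute_se = compute_se),
            class = "fit_config")
}

engine_call <- function(fl, tv, omega2, s2p, s2a, diagnostics = FALSE,
                        eta_init = NULL) {
  foce_engine_cpp(fl$obs_off, fl$obs_time, fl$dv, tv$cl, tv$v,
                  fl$dose_off, fl$dose_start, fl$dose_dur, fl$dose_rate,
                  omega2, s2p, s2a, diagnostics, eta_init)
}

#' FOCE-I objective function value
#'
#' Computes the NONMEM-style objective (-2 x approximate marginal
#' log-likelihood, without the `n log 2 pi` constant) by the first-order
#' conditional method with eta-epsilon interaction: for each subject the
#' conditional mode of the single clearance random effect is located by
#' Brent search on `[-6 omega, 6 omega]`, the model is linearized in eta at
#' the mode, and the residual variance is evaluated at the conditional
#' prediction.
#'
#' @param dataset a `population_dataset`
#' @param spec a [model_spec()]
#' @return list with `ofv`, `ofv_with_constant`
#'   (`ofv + n_obs * log(2*pi)`), per-subject `contributions`, conditional
#'   modes `eta` and a logical `unreliable` flag marking subjects whose
#'   inner search hit the bracket boundary
#' @export
foce_objective <- function(dataset, spec) {
  fl <- flatten_dataset(dataset)
  tv <- eval_typicals(spec, fl$covs)
  res <- engine_call(fl, tv, spec$iiv$omega2, spec$residual$prop^2,
                     spec$residual$add^2)
  list(ofv = res$ofv,
       ofv_with_constant = res$ofv + fl$n_obs * log(2 * pi),
       contributions = setNames(as.numeric(res$contrib), fl$ids),
       eta = setNames(as.numeric(res$eta), fl$ids),
       unreliable = any(res$at_bound))
}

#' Exact marginal objective by adaptive Gauss-Hermite quadrature
#'
#' The single random effect makes the per-subject marginal likelihood a
#' one-dimensional integral, evaluated here exactly (to quadrature
#' precision) with nodes centered and scaled at the conditional mode. All
#' accumulation happens in log space. Serves as the independent oracle for
#' the FOCE-I approximation.
#'
#' @inheritParams foce_objective
#' @param nodes number of Gauss-Hermite nodes (>= 16)
#' @return list as in [foce_objective()] (minus the `unreliable` flag)
#' @export
exact_objective_quadrature <- function(dataset, spec, nodes = 64) {
  if (nodes < 16) stop_domain("nodes must be >= 16")
  gh <- gauss_hermite(nodes)
  omega2 <- spec$iiv$omega2
  s2p <- spec$residual$prop^2
  s2a <- spec$residual$add^2
  fl <- flatten_dataset(dataset)
  tv <- eval_typicals(spec, fl$covs)

  contrib <- numeric(fl$n_subjects)
  for (i in seq_len(fl$n_subjects)) {
    o <- (fl$obs_off[i] + 1):fl$obs_off[i + 1]
    d <- (fl$dose_off[i] + 1):fl$dose_off[i + 1]
    doses <- data.frame(start = fl$dose_start[d],
                        amount = fl$dose_rate[d] * fl$dose_dur[d],
                        duration = fl$dose_dur[d])
    times <- fl$obs_time[o]
    y <- fl$dv[o]
    tvcl <- tv$cl[o]
    tvv <- tv$v[o]
    cond_ll <- function(eta) {
      f <- vapply(seq_along(times), function(j) {
        predict_concentration(list(CL = tvcl[j] * exp(eta), V = tvv[j]),
                              doses, times[j])
      }, numeric(1))
      v <- pmax(s2p * f^2 + s2a, 1e-12)
      sum(dnorm(y, f, sqrt(v), log = TRUE))
    }
    if (omega2 <= 0) {
      contrib[i] <- -2 * cond_ll(0)
      next
    }
    negl <- function(eta) -(cond_ll(eta) + dnorm(eta, 0, sqrt(omega2),
                                                 log = TRUE))
    w <- sqrt(omega2)
    mode <- optimize(negl, c(-8 * w, 8 * w), tol = 1e-10)$minimum
    h <- 1e-2 * max(w, 1e-3)
    d2 <- (negl(mode + h) - 2 * negl(mode) + negl(mode - h)) / h^2
    s <- if (is.finite(d2) && d2 > 0) 1 / sqrt(d2) else w
    lt <- vapply(seq_along(gh$nodes), function(k) {
      e <- mode + s * gh$nodes[k]
      log(gh$weights[k]) + gh$nodes[k]^2 - negl(e)
    }, numeric(1))
    contrib[i] <- -2 * (log(s) + logsumexp(lt))
  }
  total <- sum(contrib) - fl$n_obs * log(2 * pi)
  list(ofv = total,
       ofv_with_constant = sum(contrib),
       contributions = setNames(contrib - tabulate_nobs(fl) * log(2 * pi),
                                fl$ids),
       eta = NULL)
}

tabulate_nobs <- function(fl) diff(fl$obs_off)

#' Fit a population model by FOCE-I
#'
#' Minimizes the FOCE-I objective over the packed parameter vector (typical
#' values and positive hyperparameters on the log scale, exponents
#' unconstrained) with Nelder-Mead plus polish restarts. Standard errors
#' come from the inverse finite-difference Hessian of the objective
#' (covariance `2 H^{-1}`), the condition number from the eigenvalues of
#' the estimate correlation matrix. `PRED` is the population prediction at
#' `eta = 0`, `IPRED` the conditional prediction, and CWRES the
#' FOCE-linearized decorrelated residual.
#'
#' @param dataset a `population_dataset`
#' @param spec a [model_spec()] holding initial values
#' @param config a [fit_config()]
#' @param start optional named start vector on the packed (transformed)
#'   scale, e.g. `$opt_par` of an earlier fit for warm starts
#' @return an object of class `vanc_fit`
#' @export
fit <- function(dataset, spec, config = fit_config(), start = NULL) {
  if (length(dataset$subjects) == 0) stop_domain("dataset is empty")
  fl <- flatten_dataset(dataset)
  pk <- pack_parameters(spec)
  init <- pk$init
  if (!is.null(start)) {
    if (!identical(names(start), names(init)))
      stop_domain("start vector does not match the model parameterization")
    init <- start
  }

  # per-subject conditional modes are carried between objective
  # evaluations to warm-start the inner search (the C++ side falls back
  # to the full bracket whenever the narrow window is not trusted)
  eta_prev <- NULL
  objfun <- function(p) {
    sp <- pk$unpack(p)
    tv <- eval_typicals(sp, fl$covs)
    res <- tryCatch(
      engine_call(fl, tv, sp$iiv$omega2, sp$residual$prop^2,
                  sp$residual$add^2, eta_init = eta_prev),
      error = function(e) NULL)
    if (is.null(res) || !is.finite(res$ofv)) return(1e10)
    eta_prev <<- as.numeric(res$eta)
    res$ofv
  }

  opt <- optim(init, objfun, method = "Nelder-Mead",
               control = list(maxit = config$maxit, reltol = config$reltol))
  evals <- opt$counts[["function"]]
  for (r in seq_len(config$restarts)) {
    opt2 <- optim(opt$par, objfun, method = "Nelder-Mead",
                  control = list(maxit = config$maxit,
                                 reltol = config$reltol))
    evals <- evals + opt2$counts[["function"]]
    if (opt2$value <= opt$value) opt <- opt2
  }
  converged <- opt$convergence == 0 && opt$value < 1e10

  sp_hat <- pk$unpack(opt$par)
  tv <- eval_typicals(sp_hat, fl$covs)
  diag_res <- engine_call(fl, tv, sp_hat$iiv$omega2, sp_hat$residual$prop^2,
                          sp_hat$residual$add^2, diagnostics = TRUE)

  p <- length(opt$par)
  covmat <- NULL
  se_nat <- rep(NA_real_, p)
  cond_number <- Inf
  if (config$compute_se && p > 0) {
    H <- tryCatch(fd_hessian(objfun, opt$par, rel_step = config$hess_step),
                  error = function(e) NULL)
    if (!is.null(H) && all(is.finite(H))) {
      covmat <- tryCatch(2 * solve(H), error = function(e) NULL)
      if (!is.null(covmat) && all(is.finite(covmat)) &&
          all(diag(covmat) > 0)) {
        se_t <- sqrt(diag(covmat))
        cond_number <- tryCatch({
          ev <- eigen(cov2cor(covmat), symmetric = TRUE,
                      only.values = TRUE)$values
          if (min(ev) <= 0) Inf else max(ev) / min(ev)
        }, error = function(e) Inf)
        se_nat <- se_t
      } else {
        covmat <- NULL
      }
    }
  }

  # natural-scale estimates and delta-method RSEs
  nat <- vapply(seq_len(p), function(k) {
    if (pk$transform[k] == "log") exp(opt$par[[k]]) else opt$par[[k]]
  }, numeric(1))
  rse <- vapply(seq_len(p), function(k) {
    if (is.na(se_nat[k])) return(NA_real_)
    if (pk$transform[k] == "log") 100 * se_nat[k]
    else 100 * se_nat[k] / abs(nat[k])
  }, numeric(1))
  params <- data.frame(name = pk$names, estimate = nat, rse_pct = rse,
                       transform = pk$transform, stringsAsFactors = FALSE)
  # reporting-scale CVs for the variability terms
  params$cv_pct <- NA_real_
  iiv_row <- params$name == "IIV.CL.omega"
  params$cv_pct[iiv_row] <- omega2_to_cv(params$estimate[iiv_row]^2)
  res_row <- params$name == "RES.prop"
  params$cv_pct[res_row] <- 100 * params$estimate[res_row]

  ofv <- opt$value
  diag_df <- data.frame(
    id = fl$obs_id, time = fl$obs_time, dv = fl$dv,
    pred = as.numeric(diag_res$pred), ipred = as.numeric(diag_res$ipred),
    G = as.numeric(diag_res$G), v = as.numeric(diag_res$v),
    r = as.numeric(diag_res$r), stringsAsFactors = FALSE)

  out <- structure(list(
    spec = sp_hat, parameters = params, opt_par = opt$par,
    ofv = ofv, ofv_with_constant = ofv + fl$n_obs * log(2 * pi),
    aic = ofv + 2 * p, bic = ofv + p * log(fl$n_obs),
    n_par = p, n_obs = fl$n_obs, n_subjects = fl$n_subjects,
    condition_number = cond_number, cov = covmat,
    eta = data.frame(id = fl$ids, eta = as.numeric(diag_res$eta),
                     at_bound = as.logical(diag_res$at_bound),
                     stringsAsFactors = FALSE),
    diagnostics = diag_df, converged = converged,
    evaluations = evals, contributions = as.numeric(diag_res$contrib)
  ), class = "vanc_fit")
  out$diagnostics$cwres <- compute_cwres(out)
  out
}

#' @export
print.vanc_fit <- function(x, ...) {
  cat(sprintf("<vanc_fit> OFV %.3f (AIC %.3f, BIC %.3f), %d parameters, %s\n",
              x$ofv, x$aic, x$bic, x$n_par,
              if (x$converged) "converged" else "NOT converged"))
  pt <- x$parameters
  for (k in seq_len(nrow(pt))) {
    cat(sprintf("  %-16s %10.4g  (RSE %s%%)\n", pt$name[k], pt$estimate[k],
                ifelse(is.na(pt$rse_pct[k]), "NA",
                       sprintf("%.1f", pt$rse_pct[k]))))
  }
  cat(sprintf("  condition number %.3g\n", x$condition_number))
  invisible(x)
}

#' Evaluate a model on a dataset at fixed parameters
#'
#' Computes the FOCE-I objective, conditional modes and the diagnostic
#' table (PRED/IPRED/CWRES) for a given specification without estimating
#' anything — the evaluation counterpart of [fit()].
#'
#' @inheritParams foce_objective
#' @return list with `ofv`, `eta`, and a `diagnostics` data.frame
#' @export
evaluate_model <- function(dataset, spec) {
  fl <- flatten_dataset(dataset)
  tv <- eval_typicals(spec, fl$covs)
  res <- engine_call(fl, tv, spec$iiv$omega2, spec$residual$prop^2,
                     spec$residual$add^2, diagnostics = TRUE)
  d <- data.frame(id = fl$obs_id, time = fl$obs_time, dv = fl$dv,
                  pred = as.numeric(res$pred), ipred = as.numeric(res$ipred),
                  G = as.numeric(res$G), v = as.numeric(res$v),
                  r = as.numeric(res$r), stringsAsFactors = FALSE)
  out <- list(spec = spec, ofv = res$ofv,
              eta = setNames(as.numeric(res$eta), fl$ids),
              diagnostics = d)
  out$diagnostics$cwres <- compute_cwres(out)
  out
}

#' Conditional weighted residuals
#'
#' FOCE-linearized residuals decorrelated by the model-implied per-subject
#' covariance `C = diag(v) + omega2 G G'` via its Cholesky factor. Under
#' the generating model they are approximately standard normal. A singular
#' covariance falls back to an eigenvalue pseudo-inverse square root with a
#' warning.
#'
#' @param fit a `vanc_fit`
#' @param dataset unused (diagnostics travel with the fit); kept for call
#'   symmetry with the other evaluation tools
#' @return numeric vector of CWRES in observation order
#' @export
compute_cwres <- function(fit, dataset = NULL) {
  d <- fit$diagnostics
  omega2 <- fit$spec$iiv$omega2
  out <- numeric(nrow(d))
  for (id in unique(d$id)) {
    ix <- which(d$id == id)
    G <- d$G[ix]
    C <- diag(d$v[ix], nrow = length(ix)) + omega2 * tcrossprod(G)
    cw <- tryCatch(
      backsolve(chol(C), d$r[ix], transpose = TRUE),
      error = function(e) {
        warning("singular CWRES covariance for subject ", id,
                "; using pseudo-inverse", call. = FALSE)
        e2 <- eigen(C, symmetric = TRUE)
        pos <- pmax(e2$values, 1e-10)
        (e2$vectors %*% diag(1 / sqrt(pos), length(pos)) %*%
           t(e2$vectors)) %*% d$r[ix]
      })
    out[ix] <- as.numeric(cw)
  }
  out
}
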