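#' Residual unexplained variability specification
#'
#' The residual error can be additive (`Y = IPRED + e`), proportional
#' (`Y = IPRED * (1 + e)`, the first-order equivalent of the exponential
#' model `Y = IPRED * exp(e)` used by the estimator, matching common
#' NONMEM practice), or combined.
#'
#' @param form one of `"proportional"`, `"additive"`, `"combined"`
#' @param prop proportional error standard deviation (CV fraction)
#' @param add additive error standard deviation (mg/L)
#' @param estimate estimate the variance components?
#' @return an object of class `residual_spec`
#' @export
residual_spec <- function(form = c("proportional", "additive", "combined"),
                          prop = 0.3, add = 1, estimate = TRUE) {
  form <- match.arg(form)
  if (prop < 0 || add < 0) stop_domain("error SDs must be non-negative")
  has_prop <- form %in% c("proportional", "combined")
  has_add <- form %in% c("additive", "combined")
  if (!has_prop) prop <- 0
  if (!has_add) add <- 0
  if (prop <= 0 && add <= 0)
    stop_domain("at least one residual variance must be positive")
  structure(list(form = form, prop = prop, add = add,
                 estimate = estimate, has_prop = has_prop,
                 has_add = has_add),
            class = "residual_spec")
}

#' Inter-individual variability specification
#'
#' A single lognormal random effect on clearance with variance `omega2`
#' (log scale). Reported CV\% is `100 * sqrt(exp(omega2) - 1)`.
#'
#' @param cv inter-individual CV in percent (used to set `omega2` when
#'   `omega2` is missing)
#' @param omega2 variance of eta on the log scale
#' @param estimate estimate `omega2`?
#' @return an object of class `iiv_spec`
#' @export
iiv_spec <- function(cv = 30, omega2 = NULL, estimate = TRUE) {
  if (is.null(omega2)) omega2 <- log(1 + (cv / 100)^2)
  if (omega2 < 0) stop_domain("omega2 must be non-negative")
  structure(list(omega2 = omega2, estimate = estimate), class = "iiv_spec")
}

omega2_to_cv <- function(omega2) 100 * sqrt(exp(omega2) - 1)
cv_to_omega2 <- function(cv) log(1 + (cv / 100)^2)

#' Population model specification
#'
#' Assembles the structural base parameters, covariate sub-models, the
#' random-effect and residual specifications into one description that the
#' estimation engine understands.
#'
#' @param cl typical clearance (L/h) of the base individual
#' @param v typical volume (L) of the base individual
#' @param cl_covs list of [cov_spec] objects acting on clearance
#' @param v_covs list of [cov_spec] objects acting on volume
#' @param residual a [residual_spec()]
#' @param iiv an [iiv_spec()]
#' @param estimate_cl,estimate_v estimate the base typical values?
#' @return an object of class `model_spec`
#' @export
model_spec <- function(cl = 0.3, v = 2.6, cl_covs = list(),
                       v_covs = list(), residual = residual_spec(),
                       iiv = iiv_spec(), estimate_cl = TRUE,
                       estimate_v = TRUE) {
  if (cl <= 0 || v <= 0) stop_domain("cl and v must be positive")
  structure(list(cl_base = cl, v_base = v, cl_covs = cl_covs,
                 v_covs = v_covs, residual = residual, iiv = iiv,
                 estimate_cl = estimate_cl, estimate_v = estimate_v),
            class = "model_spec")
}

#' Base model: no covariates
#'
#' One-compartment model with lognormal IIV on clearance and the chosen
#' residual model, without covariate effects.
#'
#' @inheritParams model_spec
#' @export
base_model_spec <- function(cl = 0.3, v = 2.6,
                            residual = residual_spec(), iiv = iiv_spec()) {
  model_spec(cl = cl, v = v, cl_covs = list(), v_covs = list(),
             residual = residual, iiv = iiv)
}

#' Final covariate model
#'
#' Clearance scales with body weight (allometric exponent) and inversely
#' with serum creatinine; volume scales with body weight. Defaults are the
#' published estimates; pass other values (or set `estimate_*`) to use the
#' structure with free parameters.
#'
#' @param theta a [fixed_effects()] object supplying the structural values
#' @param iiv_cv inter-individual CV of clearance, percent
#' @param sigma_prop proportional residual error SD (CV fraction)
#' @return a `model_spec`
#' @export
final_model_spec <- function(theta = fixed_effects(), iiv_cv = 37.9,
                             sigma_prop = 0.375) {
  model_spec(
    cl = theta$cl_typical, v = theta$v_typical,
    cl_covs = list(
      cov_power("WT", "CL", ref = theta$wt_ref,
                theta = theta$cl_wt_exponent),
      cov_power("SCR", "CL", ref = theta$scr_ref,
                theta = theta$cl_scr_exponent, invert = TRUE)
    ),
    v_covs = list(
      cov_power("WT", "V", ref = theta$wt_ref,
                theta = theta$v_wt_exponent)
    ),
    residual = residual_spec("proportional", prop = sigma_prop),
    iiv = iiv_spec(cv = iiv_cv)
  )
}

# ---- typical-value evaluation -------------------------------------------

# covs: one row per observation, columns named like the event table.
# Multiplicative factors are applied first, additive (linear-form) terms
# afterwards; the result is floored at 1% of the multiplicative value so
# extreme covariates cannot drive a parameter negative.
eval_typicals <- function(spec, covs) {
  n <- nrow(covs)
  mult <- list(CL = rep(spec$cl_base, n), V = rep(spec$v_base, n))
  addl <- list(CL = numeric(n), V = numeric(n))
  for (cs in c(spec$cl_covs, spec$v_covs)) {
    val <- covariate_factor(cs, covs)
    if (cov_is_additive(cs)) {
      addl[[cs$parameter]] <- addl[[cs$parameter]] + val
    } else {
      mult[[cs$parameter]] <- mult[[cs$parameter]] * val
    }
  }
  list(cl = pmax(mult$CL + addl$CL, 0.01 * mult$CL),
       v = pmax(mult$V + addl$V, 0.01 * mult$V))
}

# ---- parameter packing ---------------------------------------------------

# hyperparameters constrained positive are optimized on the log scale
.log_scale_hypers <- c("tm50", "k50", "hill", "frac")

pack_parameters <- function(spec) {
  paths <- list()
  init <- numeric(0)
  trans <- character(0)
  nm <- character(0)

  push <- function(path, value, transform, name) {
    paths[[length(paths) + 1]] <<- path
    init <<- c(init, if (transform == "log") log(value) else value)
    trans <<- c(trans, transform)
    nm <<- c(nm, name)
  }

  if (isTRUE(spec$estimate_cl)) push(list("cl_base"), spec$cl_base, "log", "CL.pop")
  if (isTRUE(spec$estimate_v)) push(list("v_base"), spec$v_base, "log", "V.pop")
  for (grp in c("cl_covs", "v_covs")) {
    for (i in seq_along(spec[[grp]])) {
      cs <- spec[[grp]][[i]]
      for (h in names(cs$params)) {
        if (!isTRUE(cs$estimate[[h]])) next
        tr <- if (h %in% .log_scale_hypers) "log" else "identity"
        push(list(grp, i, "params", h), cs$params[[h]], tr,
             paste(cs$parameter, cs$covariate, h, sep = "."))
      }
    }
  }
  if (isTRUE(spec$iiv$estimate)) {
    om <- sqrt(max(spec$iiv$omega2, 1e-6))
    push(list("iiv", "omega"), om, "log", "IIV.CL.omega")
  }
  if (isTRUE(spec$residual$estimate)) {
    if (spec$residual$has_prop)
      push(list("residual", "prop"), max(spec$residual$prop, 1e-4), "log",
           "RES.prop")
    if (spec$residual$has_add)
      push(list("residual", "add"), max(spec$residual$add, 1e-4), "log",
           "RES.add")
  }
  names(init) <- nm

  unpack <- function(p) {
    sp <- spec
    for (k in seq_along(paths)) {
      val <- if (trans[k] == "log") exp(p[[k]]) else p[[k]]
      pa <- paths[[k]]
      if (identical(pa[[1]], "cl_base")) {
        sp$cl_base <- val
      } else if (identical(pa[[1]], "v_base")) {
        sp$v_base <- val
      } else if (identical(pa[[1]], "iiv")) {
        sp$iiv$omega2 <- val^2
      } else if (identical(pa[[1]], "residual")) {
        sp$residual[[pa[[2]]]] <- val
      } else {
        sp[[pa[[1]]]][[pa[[2]]]]$params[[pa[[4]]]] <- val
      }
    }
    sp
  }

  list(init = init, transform = trans, names = nm, unpack = unpack)
}
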