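#' Covariate sub-model specifications
#'
#' Constructors for the covariate-parameter relationships used throughout
#' model building. Each returns a `cov_spec` carrying the functional form,
#' the centering constant and the hyperparameters (with per-hyperparameter
#' flags saying which are estimated).
#'
#' Forms:
#' * `cov_power()`: simple allometric/exponent model
#'   `(COV/ref)^theta`, or `(ref/COV)^theta` with `invert = TRUE` (the
#'   orientation used for serum creatinine in the final model).
#' * `cov_maturation()`: size term with fixed exponent 0.75 times a sigmoid
#'   maturation factor of age. The conventional orientation
#'   `MF = 1 / (1 + (TM50/Age)^Hill)` rises from 0 to 1 with age and equals
#'   0.5 at `Age = TM50`; `printed_form = TRUE` switches to the mirrored
#'   variant `1 / (1 + (Age/TM50)^Hill)` that decreases with age.
#' * `cov_wde()` / `cov_ade()`: body-weight allometry whose exponent itself
#'   declines sigmoidally with weight (`cov_wde`) or age (`cov_ade`):
#'   `theta(x) = theta0 - kmax * x^Hill / (k50^Hill + x^Hill)`.
#' * `cov_linear()`: additive shift `slope * (COV - ref)` on the typical
#'   value (floored so the parameter stays positive).
#' * `cov_categorical()`: proportional shift, factor 1 at the reference
#'   level and `frac` otherwise.
#' * `cov_tv_baseline_delta()`: time-varying split into baseline and
#'   change-from-baseline effects,
#'   `1 + theta_bcov*(BCOV - ref) + theta_dcov*(COV - BCOV)`.
#' * `cov_tv_random()`: time-varying slope with an optional random effect,
#'   `1 + slope * exp(eta_cov) * (COV - ref)`.
#'
#' @param covariate column name of the covariate (e.g. `"WT"`, `"SCR"`)
#' @param parameter target structural parameter, `"CL"` or `"V"`
#' @param ref centering constant (typically the covariate median)
#' @param theta,theta0,kmax,k50,hill,tm50,slope,frac,theta_bcov,theta_dcov
#'   hyperparameter values (initial values when estimated)
#' @param invert use the inverted ratio `(ref/COV)^theta`
#' @param estimate logical (scalar or named) marking hyperparameters to
#'   estimate
#' @param age_cov age covariate driving the maturation / age-dependent
#'   exponent (`"PMA"`, `"GA"` or `"PNA"`)
#' @param exponent fixed allometric exponent of the maturation model
#' @param printed_form mirrored maturation orientation (see above)
#' @param ref_level reference level of a categorical covariate (coded value)
#' @param omega2_cov variance of the random slope in `cov_tv_random()`
#'   (kept at 0 by the estimator: a second random-effect dimension is not
#'   identifiable from peak/trough data)
#' @return an object of class `cov_spec`
#' @name cov_spec
NULL

new_cov_spec <- function(form, covariate, parameter, ref, params, estimate,
                         extras = list()) {
  parameter <- match.arg(parameter, c("CL", "V"))
  est <- setNames(rep(FALSE, length(params)), names(params))
  if (is.logical(estimate) && is.null(names(estimate))) {
    est[] <- estimate
  } else {
    est[names(estimate)] <- estimate
  }
  structure(c(list(form = form, covariate = covariate, parameter = parameter,
                   ref = ref, params = params, estimate = est), extras),
            class = "cov_spec")
}

#' @rdname cov_spec
#' @export
cov_power <- function(covariate, parameter = "CL", ref, theta = 1,
                      invert = FALSE, estimate = TRUE) {
  new_cov_spec("power", covariate, parameter, ref,
               params = list(theta = theta), estimate = estimate,
               extras = list(invert = invert))
}

#' @rdname cov_spec
#' @export
cov_maturation <- function(covariate = "WT", age_cov = "PMA",
                           parameter = "CL", ref, tm50 = 40, hill = 3,
                           exponent = 0.75, printed_form = FALSE,
                           estimate = TRUE) {
  if (hill <= 0) stop_domain("hill must be positive")
  new_cov_spec("maturation", covariate, parameter, ref,
               params = list(tm50 = tm50, hill = hill),
               estimate = estimate,
               extras = list(age_cov = age_cov, exponent = exponent,
                             printed_form = printed_form))
}

#' @rdname cov_spec
#' @export
cov_wde <- function(covariate = "WT", parameter = "CL", ref, theta0 = 1.5,
                    kmax = 0.5, k50 = 3, hill = 3, estimate = TRUE) {
  new_cov_spec("wde", covariate, parameter, ref,
               params = list(theta0 = theta0, kmax = kmax, k50 = k50,
                             hill = hill),
               estimate = estimate)
}

#' @rdname cov_spec
#' @export
cov_ade <- function(covariate = "WT", age_cov = "PMA", parameter = "CL",
                    ref, theta0 = 1.5, kmax = 0.5, k50 = 40, hill = 3,
                    estimate = TRUE) {
  new_cov_spec("ade", covariate, parameter, ref,
               params = list(theta0 = theta0, kmax = kmax, k50 = k50,
                             hill = hill),
               estimate = estimate, extras = list(age_cov = age_cov))
}

#' @rdname cov_spec
#' @export
cov_linear <- function(covariate, parameter = "CL", ref, slope = 0,
                       estimate = TRUE) {
  new_cov_spec("linear", covariate, parameter, ref,
               params = list(slope = slope), estimate = estimate)
}

#' @rdname cov_spec
#' @export
cov_categorical <- function(covariate, parameter = "CL", ref_level = 0,
                            frac = 1, estimate = TRUE) {
  new_cov_spec("categorical", covariate, parameter, ref = ref_level,
               params = list(frac = frac), estimate = estimate,
               extras = list(ref_level = ref_level))
}

#' @rdname cov_spec
#' @export
cov_tv_baseline_delta <- function(covariate, parameter = "CL", ref,
                                  theta_bcov = 0, theta_dcov = 0,
                                  estimate = TRUE) {
  new_cov_spec("tv_baseline_delta", covariate, parameter, ref,
               params = list(theta_bcov = theta_bcov,
                             theta_dcov = theta_dcov),
               estimate = estimate)
}

#' @rdname cov_spec
#' @export
cov_tv_random <- function(covariate, parameter = "CL", ref, slope = 0,
                          omega2_cov = 0, estimate = TRUE) {
  new_cov_spec("tv_random", covariate, parameter, ref,
               params = list(slope = slope), estimate = estimate,
               extras = list(omega2_cov = omega2_cov))
}

cov_is_additive <- function(spec) spec$form == "linear"

#' Evaluate a covariate sub-model
#'
#' Returns the dimensionless multiplier (or, for the linear form, the
#' additive term) contributed by one covariate relationship.
#'
#' @param spec a `cov_spec`
#' @param values either a numeric vector of covariate values or a
#'   data.frame/list holding the needed columns (required for forms that
#'   use two covariates, such as the maturation model, or a baseline column
#'   `B<COV>` for time-varying forms)
#' @param baseline optional explicit baseline values for the time-varying
#'   forms (otherwise taken from column `B<COV>`)
#' @param eta_cov random-slope deviation for `cov_tv_random` (default 0)
#' @return numeric vector of factors (or additive terms)
#' @export
covariate_factor <- function(spec, values, baseline = NULL, eta_cov = 0) {
  getcol <- function(name) {
    if (is.data.frame(values) || (is.list(values) && !is.null(names(values)))) {
      v <- values[[name]]
      if (is.null(v)) stop_domain(paste0("covariate '", name, "' not found"))
      v
    } else {
      values
    }
  }
  v <- getcol(spec$covariate)
  p <- spec$params
  switch(spec$form,
    power = {
      if (any(v <= 0)) stop_domain("power form needs a positive covariate")
      ratio <- if (isTRUE(spec$invert)) spec$ref / v else v / spec$ref
      ratio^p$theta
    },
    maturation = {
      if (any(v <= 0)) stop_domain("maturation form needs a positive size")
      age <- getcol(spec$age_cov)
      mf <- if (isTRUE(spec$printed_form)) {
        1 / (1 + (age / p$tm50)^p$hill)
      } else {
        1 / (1 + (p$tm50 / age)^p$hill)
      }
      (v / spec$ref)^spec$exponent * mf
    },
    wde = {
      th <- p$theta0 - p$kmax * v^p$hill / (p$k50^p$hill + v^p$hill)
      (v / spec$ref)^th
    },
    ade = {
      age <- getcol(spec$age_cov)
      th <- p$theta0 - p$kmax * age^p$hill / (p$k50^p$hill + age^p$hill)
      (v / spec$ref)^th
    },
    linear = p$slope * (v - spec$ref),
    categorical = ifelse(v == spec$ref_level, 1, p$frac),
    tv_baseline_delta = {
      b <- baseline %||% getcol(paste0("B", spec$covariate))
      1 + p$theta_bcov * (b - spec$ref) + p$theta_dcov * (v - b)
    },
    tv_random = 1 + p$slope * exp(eta_cov) * (v - spec$ref),
    stop_domain(paste0("unknown covariate form '", spec$form, "'"))
  )
}
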