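#' Fixed-effect parameters of the neonatal vancomycin model
#'
#' Bundles the five structural fixed effects of the one-compartment model
#' together with the covariate reference values at which they apply. The
#' defaults are the published estimates for a reference neonate of 2.9 kg
#' with a serum creatinine of 23.3 umol/L:
#' \deqn{CL = \theta_1 (WT/2.9)^{\theta_2} (23.3/Scr)^{\theta_3}, \quad
#'       V = \theta_4 (WT/2.9)^{\theta_5}}
#'
#' @param cl_typical typical clearance (L/h) at the reference covariates
#' @param cl_wt_exponent allometric body-weight exponent on clearance
#' @param cl_scr_exponent serum-creatinine exponent on clearance (applied to
#'   the inverted ratio `scr_ref / Scr`, so a positive value means clearance
#'   falls as creatinine rises)
#' @param v_typical typical volume of distribution (L) at `wt_ref`
#' @param v_wt_exponent body-weight exponent on volume
#' @param wt_ref reference body weight (kg)
#' @param scr_ref reference serum creatinine (umol/L)
#' @return an object of class `fixed_effects`
#' @export
fixed_effects <- function(cl_typical = 0.309, cl_wt_exponent = 1.55,
                          cl_scr_exponent = 0.337, v_typical = 2.63,
                          v_wt_exponent = 1.05, wt_ref = 2.9,
                          scr_ref = 23.3) {
  if (cl_typical <= 0 || v_typical <= 0 || wt_ref <= 0 || scr_ref <= 0)
    stop_domain("cl_typical, v_typical, wt_ref and scr_ref must be positive")
  structure(list(cl_typical = cl_typical, cl_wt_exponent = cl_wt_exponent,
                 cl_scr_exponent = cl_scr_exponent, v_typical = v_typical,
                 v_wt_exponent = v_wt_exponent, wt_ref = wt_ref,
                 scr_ref = scr_ref),
            class = "fixed_effects")
}

#' Typical (population) clearance
#'
#' Evaluates the final clearance covariate model
#' `CL = theta1 * (WT/wt_ref)^theta2 * (scr_ref/Scr)^theta3`.
#'
#' @param wt body weight (kg); vectorized
#' @param scr serum creatinine (umol/L); vectorized
#' @param theta a [fixed_effects()] object
#' @return clearance in L/h
#' @examples
#' typical_clearance(2.9, 23.3) # 0.309 L/h for the reference neonate
#' @export
typical_clearance <- function(wt, scr, theta = fixed_effects()) {
  if (any(wt <= 0) || any(scr <= 0))
    stop_domain("wt and scr must be positive")
  theta$cl_typical * (wt / theta$wt_ref)^theta$cl_wt_exponent *
    (theta$scr_ref / scr)^theta$cl_scr_exponent
}

#' Typical (population) volume of distribution
#'
#' Evaluates `V = theta4 * (WT/wt_ref)^theta5`.
#'
#' @inheritParams typical_clearance
#' @return volume in L
#' @export
typical_volume <- function(wt, theta = fixed_effects()) {
  if (any(wt <= 0)) stop_domain("wt must be positive")
  theta$v_typical * (wt / theta$wt_ref)^theta$v_wt_exponent
}

#' Individual structural parameters
#'
#' Applies the lognormal inter-individual deviation `exp(eta)` to the
#' typical clearance. Volume carries no random effect: with only peak and
#' trough samples its variability is not identifiable, so it stays at the
#' typical value.
#'
#' @param theta a [fixed_effects()] object
#' @param eta random-effect deviation on the log-clearance scale
#' @param wt body weight (kg)
#' @param scr serum creatinine (umol/L)
#' @return list with elements `CL` (L/h), `V` (L) and `ke = CL/V` (1/h)
#' @export
individual_params <- function(theta = fixed_effects(), eta = 0, wt, scr) {
  cl <- typical_clearance(wt, scr, theta) * exp(eta)
  v <- typical_volume(wt, theta)
  structure(list(CL = cl, V = v, ke = cl / v), class = "structural_params")
}

#' Closed-form concentration under multiple constant-rate infusions
#'
#' Superposition of the one-compartment IV-infusion solution over the dose
#' history. During an infusion of rate R0 started at t0 the contribution is
#' `R0/CL * (1 - exp(-ke (t - t0)))`; after the infusion ends it decays
#' mono-exponentially. Times before the first dose predict 0.
#'
#' @param params list with `CL` (L/h) and `V` (L), e.g. from
#'   [individual_params()]
#' @param doses data.frame with columns `start` (h), `amount` (mg) and
#'   `duration` (h)
#' @param times numeric vector of prediction times (h)
#' @return predicted concentrations (mg/L)
#' @export
predict_concentration <- function(params, doses, times) {
  if (params$CL <= 0 || params$V <= 0)
    stop_domain("CL and V must be positive")
  if (any(times < 0)) stop_domain("times must be non-negative")
  ke <- params$CL / params$V
  conc <- numeric(length(times))
  for (d in seq_len(nrow(doses))) {
    t0 <- doses$start[d]
    dur <- doses$duration[d]
    rate <- doses$amount[d] / dur
    te <- t0 + dur
    on <- times > t0 & times <= te
    off <- times > te
    conc[on] <- conc[on] +
      rate / params$CL * (1 - exp(-ke * (times[on] - t0)))
    conc[off] <- conc[off] +
      rate / params$CL * (1 - exp(-ke * dur)) * exp(-ke * (times[off] - te))
  }
  conc
}

#' Steady-state 24-hour area under the curve
#'
#' At steady state the daily area under the concentration-time curve equals
#' the daily dose divided by clearance, independent of the dosing schedule.
#'
#' @param daily_dose total dose per 24 h (mg)
#' @param cl clearance (L/h)
#' @return AUC over 24 h (mg*h/L)
#' @export
steady_state_auc24 <- function(daily_dose, cl) {
  if (any(cl <= 0)) stop_domain("cl must be positive")
  daily_dose / cl
}
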