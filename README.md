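# neovanc

Population pharmacokinetics of vancomycin in neonatal intensive care,
end to end in R: simulate a realistic neonatal cohort, estimate a
one-compartment nonlinear mixed-effects model with a from-scratch
FOCE-I engine, screen covariates the way neonatal PK studies do, evaluate
the model (bootstrap, CWRES, NPDE), and turn the result into
AUC-targeted dosing tables compared against published guidelines.

## Who this is for

Pharmacometricians and methods developers who want a self-contained,
tested reference implementation of the standard neonatal vancomycin
analysis pipeline — every stage is ordinary R on plain data structures,
with the estimation kernel in a small piece of C++ and an exact
quadrature oracle standing behind the FOCE-I approximation.

## The model

One-compartment disposition with first-order elimination and 2-h
constant-rate infusions; concentrations are the closed-form superposition
over the dose history. Between-subject variability is lognormal on
clearance (`CL_i = TVCL * exp(eta_i)`); residual error is proportional
(the first-order equivalent of the exponential model). The covariate
model is

    CL (L/h) = theta1 * (WT / 2.9)^theta2 * (23.3 / Scr)^theta3
    V  (L)   = theta4 * (WT / 2.9)^theta5

with body weight `WT` in kg and serum creatinine `Scr` in umol/L, and
reference estimates `theta = (0.309, 1.55, 0.337, 2.63, 1.05)`.
Estimation is first-order conditional estimation with eta–epsilon
interaction (FOCE-I): a 1-D Brent search for each subject's conditional
mode, linearization at the mode, and a NONMEM-convention objective
function value; `exact_objective_quadrature()` provides the adaptive
Gauss–Hermite oracle the test suite pins the approximation against.
Dosing uses the steady-state identity `daily dose = 400 x MIC x CL` for
the efficacy target `AUC24/MIC >= 400` (800 as the upper bound).

## Worked example

```r
library(neovanc)

# the reference neonate: 2.9 kg, serum creatinine 23.3 umol/L
typical_clearance(2.9, 23.3)   # 0.309  (L/h)
typical_volume(2.9)            # 2.63   (L)

# dose implied by the AUC24/MIC >= 400 target for 3.0 kg, Scr 25 umol/L
cl <- typical_clearance(3.0, 25)                 # 0.3180334 L/h
daily_dose_for_target(cl)                        # 127.2133 mg/day
daily_dose_for_target(cl) / 3 / 3.0              # 14.13482 mg/kg per q8h dose
# -> inside the published 12.5-15 mg/kg q8h recommendation for this band

# simulate a cohort with the study's design and refit it
sim <- simulate_cohort(cohort_config(n_subjects = 80, seed = 42))
f <- fit(sim$dataset, final_model_spec(
  theta = fixed_effects(cl_typical = 0.3, cl_wt_exponent = 1.3,
                        cl_scr_exponent = 0.3, v_typical = 2.5,
                        v_wt_exponent = 1.0),
  iiv_cv = 30, sigma_prop = 0.3))
f
#> <vanc_fit> OFV 680.358 (AIC 694.358, BIC 715.885), 7 parameters, converged
#>   CL.pop                0.312  (RSE 4.9%)
#>   V.pop                 2.983  (RSE 9.6%)
#>   CL.WT.theta           1.685  (RSE 9.0%)
#>   CL.SCR.theta         0.3471  (RSE 31.5%)
#>   V.WT.theta             1.23  (RSE 28.8%)
#>   IIV.CL.omega         0.3479  (RSE 11.2%)
#>   RES.prop             0.3218  (RSE 8.6%)
#>   condition number 2.14
```

The fitted typical clearance (0.312 L/h) recovers the generating 0.309
within 1%; the exponents are noisier, as their reference RSEs (10–40%)
predict for a two-samples-per-subject design. Downstream:
`run_covariate_search()` for the four-step covariate screen,
`bootstrap()` / `npde()` / `gof_tables()` / `flag_outliers()` for
evaluation, `build_dose_table()` and `compare_to_guidelines()` for dosing
design, and `vanc_cli()` for the scripted front end
(`simulate | fit | covsearch | bootstrap | npde | dosing-table |
guideline-compare`).

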