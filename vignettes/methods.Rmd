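---
title: "Methods: neonatal vancomycin population pharmacokinetics in neovanc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: neonatal vancomycin population pharmacokinetics in neovanc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

Vancomycin in neonates is described by a one-compartment disposition model
with first-order elimination and constant-rate (2-hour) intravenous
infusions. Concentrations are the superposition of the closed-form
infusion solution over the dose history: during an infusion of rate $R_0$
started at $t_0$ the contribution is $\frac{R_0}{CL}(1 - e^{-k_e(t-t_0)})$
with $k_e = CL/V$, decaying mono-exponentially after the infusion ends.
Only peak (1 h after the end of infusion) and trough (0.5 h before the
next dose) samples are available in the population this package emulates,
which is why a richer two-compartment structure is out of reach and why
the volume of distribution carries no random effect.

Between-subject variability is lognormal on clearance,
$CL_i = \widehat{CL}_i\,e^{\eta_i}$, $\eta_i \sim N(0, \omega^2)$.
Residual error is proportional, the first-order equivalent of the
exponential form $y = f\,e^{\varepsilon}$; the estimator uses
$\mathrm{Var}(y) = \sigma^2 f^2$ evaluated at the conditional prediction
(the eta--epsilon "interaction").

The final covariate model is
$$CL\ (\mathrm{L/h}) = \theta_1 \left(\frac{WT}{2.9}\right)^{\theta_2}
 \left(\frac{23.3}{Scr}\right)^{\theta_3}, \qquad
 V\ (\mathrm{L}) = \theta_4 \left(\frac{WT}{2.9}\right)^{\theta_5},$$
with body weight in kg and serum creatinine in umol/L; the bundled
reference estimates are $\theta = (0.309, 1.55, 0.337, 2.63, 1.05)$.

## Estimation: FOCE-I with an exact oracle

The marginal likelihood is approximated by first-order conditional
estimation with interaction. Because the random effect is
one-dimensional, each subject's conditional mode $\hat\eta_i$ is found by
Brent search on $[-6\omega, 6\omega]$; the model is linearized in $\eta$
at the mode, giving the per-subject contribution
$\log|C_i| + r_i^\top C_i^{-1} r_i$ with
$C_i = \mathrm{diag}(v_i) + \omega^2 G_i G_i^\top$ and
$r_i = y_i - f_i(\hat\eta_i) + G_i\hat\eta_i$, computed via the rank-one
Woodbury identity. The reported OFV follows the NONMEM convention
(no $n\log 2\pi$ constant); `ofv_with_constant` carries the alternative,
and every comparison in the package uses differences, which are invariant
to the convention.

The same one-dimensionality makes an essentially exact check cheap:
`exact_objective_quadrature()` evaluates each subject's marginal
likelihood by adaptive Gauss--Hermite quadrature centered and scaled at
the conditional mode, in log space. The test suite pins the quadrature
against brute-force trapezoid integration and then pins FOCE-I against
the quadrature: agreement is exact as $\omega^2 \to 0$ and within 0.5 per
subject at study-level variability. Node-doubling convergence is
demonstrated on an additive-error cohort; the proportional-error
integrand is measurably non-Gaussian and converges about three orders of
magnitude more slowly.

The outer problem optimizes typical values and positive hyperparameters
on the log scale (exponents unconstrained) with Nelder--Mead plus a
polish restart (relative tolerance `1e-9`, 1500 iterations per stage, all
configurable via `fit_config()`). Standard errors come from the central
finite-difference Hessian of the OFV (covariance $2H^{-1}$, relative step
`1e-4`); the condition number is the eigenvalue ratio of the estimate
correlation matrix, with 1000 as the instability threshold used in model
selection. Degenerate cases are defined rather than accidental: at
$\omega^2 = 0$ the objective reduces to extended least squares, residual
variances are floored at `1e-12`, and an inner mode on the bracket
boundary flags the subject and the fit.

## The synthetic cohort: what it emulates and what it does not

`simulate_cohort()` reproduces the *design* of the source cohort: 80
neonates, gestational age truncated-normal 34.7 +/- 4.31 (25.7--41.1 wk),
postnatal age lognormal with median 24 d (4--126 d) rejected until
postmenstrual age lands in the observed 29--47.1 wk, weight an increasing
function of PMA (the embedded growth lookup scaled by 0.84, calibrated
once so the simulated median weight matches the cohort's 2.74 kg --- ICU
neonates sit below healthy-median growth) with 10% lognormal noise
truncated to 1.4--5.6 kg, and serum creatinine lognormal matching the
reported mean 23.2 / SD 10.4 umol/L on 5.85--61.6 (`scr_target =
"median"` switches to the reported median 28.3; the two printed summaries
are mutually inconsistent, and the model's centering constant stays at
the printed 23.3 either way). Dosing is 10--15 mg/kg per dose q8h or
q12h as 2-h infusions; each subject contributes two samples from the
peak/trough slots after the fourth dose with the study's 90/165 peak
fraction. Laboratory covariates and co-medication flags are simulated
with *no* effect on clearance, so they act as true-null candidates for
the covariate search.

Two conventions worth stating. The generator draws
$\omega^2 = \log(1 + \mathrm{CV}^2)$ so the *empirical* CV of simulated
clearance equals the configured 37.9%, and fits report the IIV CV with
the inverse transform, keeping generation and reporting consistent.
Residual noise is generated multiplicatively ($y = f e^{\varepsilon}$,
which keeps concentrations positive) with
$\mathrm{sd}(\varepsilon) = \sqrt{\log(1 + 0.375^2)}$ and fitted by the
proportional model, whose $\hat\sigma$ then estimates the multiplicative
CV of 0.375.

What a green test does **not** establish: the generator draws covariates
independently apart from the weight--age link (real cohorts correlate
creatinine with age), keeps covariates constant within subject (the
course is short; tests that exercise the time-varying sub-models inject
drift explicitly), has no dropout, no assay censoring beyond flagging,
and no model misspecification. Parameter-recovery results quantify the
information content of this idealized design, not robustness to real
data pathology.

## Covariate search

The four-step screen mirrors standard neonatal practice. Step 1 compares
four size/maturation structures on clearance (simple allometric
exponent; fixed-0.75 exponent times a sigmoid maturation factor of age;
weight- and age-dependent exponent models), each with a weight power on
volume, ranking by AIC and rejecting candidates whose condition number
exceeds 1000 or whose clearance-side RSEs exceed 100%. The volume
exponent is excluded from that RSE screen: it is carried for
physiological plausibility, not under selection, and is weakly
identified before creatinine enters the model. The three age descriptors
(GA, PNA, PMA) are screened one at a time within the age-driven families
because they are collinear by construction.

The printed maturation factor decreases with age, contradicting the
definition of TM50 in the same description; the package defaults to the
conventional orientation $MF = 1/(1+(TM_{50}/\mathrm{Age})^{Hill})$
(rising from 0 to 1, 0.5 at TM50) and retains the printed form behind
`printed_form = TRUE`.

Step 2 adds serum creatinine as either an (inverted) power or a linear
form and keeps the better fit unconditionally --- renal elimination is
established prior knowledge, so no significance gate applies; both OFV
drops are recorded for audit. Step 3 runs forward inclusion (largest
drop > 3.83, chi-squared df = 1, p < 0.05; deterministic tie-break by
candidate order; an accepted age descriptor evicts its collinear
siblings) followed by backward elimination over the step-3 additions
(removal unless exclusion raises the OFV by more than 6.63, p < 0.01;
removed covariates cannot re-enter). Step 4 refits each within-subject
time-varying continuous covariate as a baseline/change-from-baseline
decomposition or a slope form, retaining a variant only for an OFV
improvement above 6.63; the slope's own random effect is held at zero
because a second random-effect dimension is not identifiable from two
samples per subject.

## Model evaluation

Conditional weighted residuals decorrelate the FOCE-linearized residual
by the Cholesky factor of $C_i$; the +/-6 screen defines outliers. A
caveat the tests make explicit: under proportional error, a 10-fold
corruption of a *small* trough can legitimately hide inside the
conditional variance, so the sensitivity check perturbs a full-sized
peak. The nonparametric bootstrap resamples subjects (not observations,
preserving within-subject correlation), refits from the original point
estimates for speed, and summarizes medians, 2.5/97.5 percentiles and
relative bias, with non-converged replicates counted against the success
fraction; a fraction below 50% flags the summary unreliable. NPDE
simulates the fitted model at the observed design, decorrelates observed
and simulated vectors with the empirical simulation covariance
(ridge-regularized on failure), transforms clipped mid-ranks to normal
quantiles, and combines the mean-zero t-test, a chi-squared variance
test and Shapiro--Wilk normality by Bonferroni --- which makes the
global test conservative: its realized size in the calibration tests
sits below the nominal 5%.

## Dosing design

The efficacy target is $AUC_{24}/MIC \ge 400$ with 800 adopted as the
upper (toxicity-avoidance) bound; at steady state the required daily
dose is $400 \times MIC \times CL$ exactly, and the assumption is
justified by sampling after at least four doses. Dose tables simulate
1000 virtual patients per scenario over the 28--44 wk PMA grid (weights
from the embedded growth lookup; the creatinine grid defaults to the
published table's {10, 25, 45, 60} umol/L, with the alternative {15, 20,
35} and {15, 35} grids available because the source document disagrees
with itself across sections), score every (2.5 mg/kg-grid amount,
interval) pair by the fraction of patients inside [400, 800), and break
ties toward fewer daily administrations, then lower dose. The guideline
comparison classifies each published reference's daily dose range
against the 15--85 percentile interval of the per-patient *required*
daily dose; scenarios outside a guideline's bands are reported
not-covered rather than guessed. Creatinine scenarios above the
observed 61.6 umol/L warn about extrapolation. The growth lookup is a
synthetic compilation of healthy-infant median weights chosen to map the
PMA grid into the published weight bands; it ships with the package so
everything runs self-contained.

## Known limitations

* Estimates of the creatinine and volume exponents are intrinsically
  noisy at this design's information content (two samples per subject):
  single-replicate errors of 30--100% are expected and observed, matching
  the reference RSEs of 40% and 27%. Only the typical-clearance
  parameter is tightly identified, and the acceptance experiments
  reflect that.
* The FOCE-I objective is a linearization; its agreement with the exact
  quadrature (within 0.5 per subject here) degrades with larger
  residual CVs or fewer observations per subject.
* No censored-data likelihood: below-detection observations are flagged
  and retained, matching the source analysis's silence on the subject.
* The command-line layer writes flat CSV/JSON artifacts with seed and
  configuration fingerprints; it does not manage run directories or
  parallelism.
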