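Package: neovanc
Title: Population Pharmacokinetic Modelling and Dose Design for Vancomycin
    in Neonates
Version: 0.1.0
Authors@R:
    person("neovanc", "developers", email = "neovanc@example.org",
           role = c("aut", "cre"))
Description: Tools for one-compartment population pharmacokinetic analysis
    of vancomycin in neonatal intensive-care cohorts: simulation of virtual
    cohorts with realistic demographics, dosing and peak/trough sampling;
    first-order conditional estimation with eta-epsilon interaction (FOCE-I)
    implemented from scratch together with an exact adaptive Gauss-Hermite
    oracle; allometric scaling and maturation covariate sub-models with a
    four-step stepwise covariate search; model evaluation by nonparametric
    bootstrap, conditional weighted residuals and normalized prediction
    distribution errors; and Monte Carlo construction of AUC24/MIC-targeted
    dosing tables with comparison against published neonatal dosing
    guidelines.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
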