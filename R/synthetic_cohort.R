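#' Cohort generator configuration
#'
#' Describes the virtual neonatal ICU cohort: demographic marginals match
#' the study population (gestational age truncated normal 34.7 +/- 4.31 wk
#' on 25.7-41.1; postnatal age lognormal with median 24 d on 4-126; weight
#' an increasing function of postmenstrual age scaled to the cohort's
#' median 2.74 kg with 10% lognormal noise, truncated to 1.4-5.6 kg; serum
#' creatinine lognormal with mean 23.2 and SD 10.4 umol/L on 5.85-61.6, or
#' median 28.3 via `scr_target = "median"`). Dosing is 10-15 mg/kg per
#' dose every 8 h or 12 h as 2-h infusions; two samples per subject are
#' drawn from the peak/trough slots after at least four doses with the
#' study's 90/165 peak fraction.
#'
#' @param n_subjects number of virtual neonates
#' @param seed RNG seed recorded in the provenance
#' @param ga_mean,ga_sd,ga_range gestational age distribution (weeks)
#' @param pna_meanlog,pna_sdlog,pna_range postnatal age distribution (days)
#' @param pma_range admissible postmenstrual age range (weeks); the
#'   postnatal-age draw is rejected until `GA + PNA/7` falls inside it
#' @param wt_range,wt_cv,wt_scale weight truncation range (kg), lognormal
#'   CV, and the cohort scaling applied to the reference growth curve
#'   (ICU neonates run below the healthy-infant median)
#' @param scr_mean,scr_sd,scr_range,scr_target serum creatinine settings
#' @param p_male probability of male sex (54/80 in the study)
#' @param p_comed marginal probability of each co-medication flag
#' @param dose_per_kg per-dose range (mg/kg)
#' @param intervals admissible dosing intervals (h)
#' @param infusion_duration infusion length (h)
#' @param n_doses doses per subject (>= 5 so sampling after four doses is
#'   possible; the default 7 leaves room for two sampling slots)
#' @param samples_per_subject concentration samples per subject
#' @param p_peak probability a sample is a peak rather than a trough
#' @param theta generating [fixed_effects()]
#' @param iiv_cv inter-individual CV of clearance, percent (the empirical
#'   CV of simulated clearance converges to this value)
#' @param sigma_cv residual proportional CV, percent
#' @return an object of class `cohort_config`
#' @export
cohort_config <- function(n_subjects = 80, seed = NULL,
                          ga_mean = 34.7, ga_sd = 4.31,
                          ga_range = c(25.7, 41.1),
                          pna_meanlog = log(24), pna_sdlog = 0.77,
                          pna_range = c(4, 126),
                          pma_range = c(29, 47.1),
                          wt_range = c(1.4, 5.6), wt_cv = 0.10,
                          wt_scale = 0.84,
                          scr_mean = 23.2, scr_sd = 10.4,
                          scr_range = c(5.85, 61.6),
                          scr_target = c("mean_sd", "median"),
                          p_male = 54 / 80, p_comed = 0.3,
                          dose_per_kg = c(10, 15), intervals = c(8, 12),
                          infusion_duration = 2, n_doses = 7,
                          samples_per_subject = 2, p_peak = 90 / 165,
                          theta = fixed_effects(), iiv_cv = 37.9,
                          sigma_cv = 37.5) {
  scr_target <- match.arg(scr_target)
  if (n_subjects < 1) stop_domain("n_subjects must be >= 1")
  if (n_doses < 5) stop_domain("need at least 5 doses for valid sampling")
  if (n_doses < 5 + samples_per_subject)
    stop_domain("n_doses must be >= 5 + samples_per_subject")
  if (ga_range[1] >= ga_range[2] || wt_range[1] >= wt_range[2] ||
      scr_range[1] >= scr_range[2] || pna_range[1] >= pna_range[2])
    stop_domain("empty truncation region in cohort configuration")
  structure(as.list(environment()), class = "cohort_config")
}

#' Sample neonatal demographics
#'
#' Draws covariate vectors for `n` subjects from the configured marginals.
#' Postmenstrual age is derived as `PMA = GA + PNA/7`; weight is the scaled
#' reference growth-curve median at that PMA times lognormal noise, so the
#' weight-age correlation that the dosing design relies on is preserved.
#' Laboratory covariates (BUN, albumin, AST, ALT) and co-medication flags
#' are simulated with no effect on clearance; they act as null candidates
#' for the covariate search.
#'
#' @param n number of subjects
#' @param config a [cohort_config()]
#' @return data.frame with one row per subject
#' @export
sample_demographics <- function(n, config = cohort_config()) {
  cf <- config
  ga <- rtrunc(n, function(m) rnorm(m, cf$ga_mean, cf$ga_sd),
               cf$ga_range[1], cf$ga_range[2])
  # PNA is redrawn until PMA = GA + PNA/7 lands in the observed PMA range,
  # mirroring the joint age structure of the cohort
  pna <- vapply(ga, function(g) {
    lo <- max(cf$pna_range[1], (cf$pma_range[1] - g) * 7)
    hi <- min(cf$pna_range[2], (cf$pma_range[2] - g) * 7)
    rtrunc(1, function(m) rlnorm(m, cf$pna_meanlog, cf$pna_sdlog),
           max(lo, cf$pna_range[1]), max(hi, lo + 1e-9))
  }, numeric(1))
  pma <- ga + pna / 7
  wt_sdlog <- sqrt(log(1 + cf$wt_cv^2))
  wt_med <- cf$wt_scale * growth_weight_median(pma)
  wt <- vapply(seq_len(n), function(i) {
    rtrunc(1, function(m) wt_med[i] * rlnorm(m, 0, wt_sdlog),
           cf$wt_range[1], cf$wt_range[2])
  }, numeric(1))
  if (cf$scr_target == "median") {
    scr_meanlog <- log(28.3)
    scr_sdlog <- 0.43
  } else {
    cv2 <- (cf$scr_sd / cf$scr_mean)^2
    scr_sdlog <- sqrt(log(1 + cv2))
    scr_meanlog <- log(cf$scr_mean) - scr_sdlog^2 / 2
  }
  scr <- rtrunc(n, function(m) rlnorm(m, scr_meanlog, scr_sdlog),
                cf$scr_range[1], cf$scr_range[2])
  sex <- rbinom(n, 1, 1 - cf$p_male) # 0 male, 1 female
  labs <- data.frame(
    BUN = rtrunc(n, function(m) rlnorm(m, log(4.1), 0.75), 0.4, 28.5),
    ALB = rtrunc(n, function(m) rnorm(m, 32.4, 5.49), 21.6, 46.8),
    AST = rtrunc(n, function(m) rlnorm(m, log(18), 0.9), 3, 575),
    ALT = rtrunc(n, function(m) rlnorm(m, log(41), 0.9), 9, 696)
  )
  meds <- as.data.frame(setNames(
    lapply(c("CEF", "MER", "GEN", "FUR", "IBU", "DEX"),
           function(x) rbinom(n, 1, cf$p_comed)),
    c("CEF", "MER", "GEN", "FUR", "IBU", "DEX")))
  cbind(data.frame(GA = ga, PNA = pna, PMA = pma, WT = wt, SCR = scr,
                   SEX = sex), labs, meds)
}

#' Build a dosing regimen
#'
#' Per-dose amounts are drawn uniformly in `dose_per_kg` times body weight;
#' the interval is drawn from `intervals`; all infusions last
#' `infusion_duration` hours.
#'
#' @param wt body weight (kg)
#' @param config a [cohort_config()]
#' @return data.frame of dose events (`start`, `amount`, `duration`)
#' @export
build_regimen <- function(wt, config = cohort_config()) {
  cf <- config
  interval <- if (length(cf$intervals) == 1) cf$intervals
              else cf$intervals[sample.int(length(cf$intervals), 1)]
  amounts <- runif(cf$n_doses, cf$dose_per_kg[1], cf$dose_per_kg[2]) * wt
  data.frame(start = (seq_len(cf$n_doses) - 1) * interval,
             amount = amounts, duration = cf$infusion_duration)
}

#' Schedule peak/trough samples
#'
#' Peaks are drawn 1 h after the end of the infusion, troughs half an hour
#' before the next dose, with sampling restricted to after the fourth dose.
#' Slot `s` anchors on dose `4 + s`.
#'
#' @param regimen a dose-event data.frame from [build_regimen()]
#' @param config a [cohort_config()]
#' @return data.frame with `time` and `kind`
#' @export
schedule_samples <- function(regimen, config = cohort_config()) {
  cf <- config
  if (nrow(regimen) < 5)
    stop_domain("regimen must contain at least 5 doses")
  kinds <- ifelse(runif(cf$samples_per_subject) < cf$p_peak,
                  "peak", "trough")
  times <- vapply(seq_len(cf$samples_per_subject), function(s) {
    anchor <- 4 + s
    if (kinds[s] == "peak") {
      regimen$start[anchor] + regimen$duration[anchor] + 1
    } else {
      regimen$start[anchor + 1] - 0.5
    }
  }, numeric(1))
  ord <- order(times)
  data.frame(time = times[ord], kind = kinds[ord],
             stringsAsFactors = FALSE)
}

#' Simulate a virtual cohort
#'
#' Draws demographics, regimens and sampling times, applies the generating
#' model (`CL` and `V` from the covariate equations, lognormal
#' inter-individual deviation on clearance, exponential residual error
#' whose empirical CV equals `sigma_cv`), and returns the dataset together
#' with the per-subject truth needed for recovery tests. Concentrations
#' below the 1 mg/L detection limit are flagged (and retained); with both
#' variability terms switched off the data reproduce the structural
#' predictions exactly.
#'
#' @param config a [cohort_config()]
#' @return list with `dataset` (a `population_dataset`) and `truth`
#'   (data.frame: `id`, `eta`, `CL_true`, `V_true`)
#' @export
simulate_cohort <- function(config = cohort_config()) {
  cf <- config
  if (!is.null(cf$seed)) set.seed(cf$seed)
  demo <- sample_demographics(cf$n_subjects, cf)
  omega2 <- cv_to_omega2(cf$iiv_cv)
  sig_sdlog <- sqrt(log(1 + (cf$sigma_cv / 100)^2))

  subjects <- vector("list", cf$n_subjects)
  truth <- data.frame(id = character(cf$n_subjects), eta = NA_real_,
                      CL_true = NA_real_, V_true = NA_real_,
                      stringsAsFactors = FALSE)
  for (i in seq_len(cf$n_subjects)) {
    id <- sprintf("S%03d", i)
    regimen <- build_regimen(demo$WT[i], cf)
    samples <- schedule_samples(regimen, cf)
    eta <- if (omega2 > 0) rnorm(1, 0, sqrt(omega2)) else 0
    pars <- individual_params(cf$theta, eta, demo$WT[i], demo$SCR[i])
    f <- predict_concentration(pars, regimen, samples$time)
    eps <- if (sig_sdlog > 0) rnorm(nrow(samples), 0, sig_sdlog) else 0
    y <- f * exp(eps)
    obs <- data.frame(time = samples$time, value = y, kind = samples$kind,
                      below_detection = y < 1, below_calibration = y < 3,
                      stringsAsFactors = FALSE)
    covs <- cbind(data.frame(time = 0), demo[i, , drop = FALSE])
    rownames(covs) <- NULL
    subjects[[i]] <- subject_record(id, covs, regimen, obs)
    truth$id[i] <- id
    truth$eta[i] <- eta
    truth$CL_true[i] <- pars$CL
    truth$V_true[i] <- pars$V
  }
  ds <- population_dataset(subjects, provenance = list(
    generator = "simulate_cohort", seed = cf$seed,
    n_subjects = cf$n_subjects, iiv_cv = cf$iiv_cv,
    sigma_cv = cf$sigma_cv))
  list(dataset = ds, truth = truth)
}
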