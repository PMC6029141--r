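#' Covariate search settings
#'
#' @param forward_dofv OFV drop required for forward inclusion
#'   (chi-squared, df = 1, p < 0.05)
#' @param backward_dofv OFV rise required to keep a covariate during
#'   backward elimination (df = 1, p < 0.01)
#' @param tv_dofv OFV drop required to retain a time-varying refinement
#' @param condition_limit instability threshold on the condition number
#' @param rse_limit instability threshold on any parameter RSE (percent)
#' @param estimation a [fit_config()] used for every fit in the search
#' @return a list of class `search_config`
#' @export
search_config <- function(forward_dofv = 3.83, backward_dofv = 6.63,
                          tv_dofv = 6.63, condition_limit = 1000,
                          rse_limit = 100, estimation = fit_config()) {
  structure(list(forward_dofv = forward_dofv, backward_dofv = backward_dofv,
                 tv_dofv = tv_dofv, condition_limit = condition_limit,
                 rse_limit = rse_limit, estimation = estimation),
            class = "search_config")
}

fit_quiet <- function(dataset, spec, config) {
  tryCatch(suppressWarnings(fit(dataset, spec, config)),
           error = function(e) NULL)
}

# Stability screen: condition number and RSEs. `exclude` drops parameters
# from the RSE criterion; step 1 excludes the volume-side terms, which are
# carried for physiological plausibility rather than being under selection
# (the study's step-1 comparison table reports clearance-side parameters).
is_stable <- function(f, sc, exclude = NULL) {
  if (is.null(f) || !f$converged) return(FALSE)
  if (!is.finite(f$condition_number) ||
      f$condition_number > sc$condition_limit) return(FALSE)
  keep <- rep(TRUE, nrow(f$parameters))
  if (!is.null(exclude)) keep <- !grepl(exclude, f$parameters$name)
  rse <- f$parameters$rse_pct[keep]
  if (any(is.na(rse)) || any(rse > sc$rse_limit)) return(FALSE)
  TRUE
}

fit_row <- function(label, f, sc, extra = "", exclude = NULL) {
  data.frame(model = label, detail = extra,
             ofv = if (is.null(f)) NA_real_ else f$ofv,
             aic = if (is.null(f)) NA_real_ else f$aic,
             bic = if (is.null(f)) NA_real_ else f$bic,
             condition = if (is.null(f)) NA_real_ else f$condition_number,
             max_rse = if (is.null(f)) NA_real_
                       else suppressWarnings(max(f$parameters$rse_pct)),
             stable = !is.null(f) && is_stable(f, sc, exclude),
             stringsAsFactors = FALSE)
}

dataset_medians <- function(dataset) {
  bc <- baseline_covariates(dataset)
  vapply(.cont_cov_cols, function(cc) median(bc[[cc]], na.rm = TRUE),
         numeric(1))
}

add_cl_cov <- function(spec, cs) {
  spec$cl_covs <- c(spec$cl_covs, list(cs))
  spec
}

drop_cl_cov <- function(spec, covariate) {
  keep <- vapply(spec$cl_covs, function(x) x$covariate != covariate,
                 logical(1))
  spec$cl_covs <- spec$cl_covs[keep]
  spec
}

#' Names of the clearance covariates in a model specification
#'
#' @param spec a [model_spec()]
#' @return character vector of covariate column names
#' @export
cl_cov_names <- function(spec)
  vapply(spec$cl_covs, function(x) x$covariate, character(1))

#' Step 1: size and maturation model selection
#'
#' Fits the four candidate size models on clearance (simple allometric
#' exponent; fixed-0.75 exponent with a sigmoid maturation factor of age;
#' weight-dependent exponent; age-dependent exponent), each with a
#' body-weight power on volume, and ranks them by AIC. Within the two
#' age-driven families the best single age descriptor (GA, PNA or PMA, by
#' AIC) represents the family. Models with a condition number above the
#' instability threshold or any RSE above 100% are rejected as unstable;
#' the surviving model with the lowest AIC is carried forward.
#'
#' @param dataset a `population_dataset`
#' @param config a [search_config()]
#' @return list with the candidate `table`, the winning `best` label,
#'   `fit` and `spec`
#' @export
step1_size_models <- function(dataset, config = search_config()) {
  med <- dataset_medians(dataset)
  vc <- list(cov_power("WT", "V", ref = med[["WT"]], theta = 1))
  ages <- c("GA", "PNA", "PMA")

  mk <- function(cl_cov) model_spec(cl = 0.3, v = 2.6,
                                    cl_covs = list(cl_cov), v_covs = vc)

  best_of_family <- function(make_spec, label) {
    fits <- lapply(ages, function(a) fit_quiet(dataset, make_spec(a),
                                               config$estimation))
    aics <- vapply(fits, function(f) if (is.null(f)) Inf else f$aic,
                   numeric(1))
    k <- which.min(aics)
    list(fit = fits[[k]], age = ages[k], label = label)
  }

  cand <- list(
    list(fit = fit_quiet(dataset, mk(cov_power("WT", ref = med[["WT"]],
                                               theta = 1)),
                         config$estimation),
         age = "", label = "I: simple exponent"),
    best_of_family(function(a) mk(cov_maturation(
      "WT", age_cov = a, ref = med[["WT"]], tm50 = med[[a]], hill = 3)),
      "II: maturation"),
    list(fit = fit_quiet(dataset, mk(cov_wde(
      "WT", ref = med[["WT"]], theta0 = 1.5, kmax = 0.3,
      k50 = med[["WT"]], hill = 3)), config$estimation),
      age = "", label = "III: WT-dependent exponent"),
    best_of_family(function(a) mk(cov_ade(
      "WT", age_cov = a, ref = med[["WT"]], theta0 = 1.5, kmax = 0.3,
      k50 = med[[a]], hill = 3)), "IV: age-dependent exponent")
  )

  table <- do.call(rbind, lapply(cand, function(cc)
    fit_row(cc$label, cc$fit, config, cc$age, exclude = "^V\\.")))
  stable_aic <- ifelse(table$stable, table$aic, Inf)
  if (all(!is.finite(stable_aic)))
    stop_domain(paste0("all size models unstable; simplify the model or ",
                       "check the data"))
  k <- which.min(stable_aic)
  list(table = table, best = table$model[k], fit = cand[[k]]$fit,
       spec = cand[[k]]$fit$spec)
}

#' Step 2: renal-function model on clearance
#'
#' Adds serum creatinine to the step-1 model as either a power term on the
#' inverted ratio or a linear shift and keeps the better-fitting form
#' (equal parameter counts, so lower OFV decides). Creatinine enters as a
#' prior-knowledge covariate — renal elimination is established
#' pharmacology — so no significance gate is applied; the OFV drop of both
#' forms is recorded for audit.
#'
#' @param dataset a `population_dataset`
#' @param step1 result of [step1_size_models()] (or any list with `fit`)
#' @param config a [search_config()]
#' @return list with the candidate `table` (including delta-OFV vs the
#'   base), `included` flag, winning `fit` and `spec`
#' @export
step2_renal_models <- function(dataset, step1,
                               config = search_config()) {
  base_fit <- step1$fit
  med <- dataset_medians(dataset)
  cands <- list(
    power = add_cl_cov(base_fit$spec,
                       cov_power("SCR", ref = med[["SCR"]], theta = 0,
                                 invert = TRUE)),
    linear = add_cl_cov(base_fit$spec,
                        cov_linear("SCR", ref = med[["SCR"]], slope = 0))
  )
  fits <- lapply(cands, function(sp) fit_quiet(dataset, sp,
                                               config$estimation))
  table <- rbind(fit_row("Scr power", fits$power, config),
                 fit_row("Scr linear", fits$linear, config))
  table$dofv <- base_fit$ofv - table$ofv
  ofvs <- vapply(fits, function(f) if (is.null(f)) Inf else f$ofv,
                 numeric(1))
  if (all(!is.finite(ofvs))) {
    return(list(table = table, included = FALSE, fit = base_fit,
                spec = base_fit$spec))
  }
  k <- which.min(ofvs)
  list(table = table, included = TRUE, fit = fits[[k]],
       spec = fits[[k]]$spec, form = names(cands)[k])
}

#' Default step-3 candidate set
#'
#' Power forms for the continuous covariates not already in the model
#' (the three age descriptors are treated as one collinear group: once one
#' enters, the others leave the candidate list) and proportional forms for
#' sex and the co-medication flags.
#'
#' @param dataset a `population_dataset`
#' @param spec current model (used to exclude present covariates)
#' @return named list of [cov_spec] candidates with a `group` attribute
#' @export
default_candidates <- function(dataset, spec) {
  med <- dataset_medians(dataset)
  bc <- baseline_covariates(dataset)
  present <- cl_cov_names(spec)
  out <- list()
  grp <- character(0)
  for (cc in c("GA", "PNA", "PMA", "BUN", "ALB", "AST", "ALT")) {
    if (cc %in% present || all(is.na(bc[[cc]]))) next
    out[[cc]] <- cov_power(cc, ref = med[[cc]], theta = 0)
    grp <- c(grp, if (cc %in% c("GA", "PNA", "PMA")) "age" else cc)
  }
  for (cc in c("SEX", "CEF", "MER", "GEN", "FUR", "IBU", "DEX")) {
    if (cc %in% present || all(is.na(bc[[cc]])) ||
        length(unique(bc[[cc]])) < 2) next
    out[[cc]] <- cov_categorical(cc, ref_level = 0, frac = 1)
    grp <- c(grp, cc)
  }
  attr(out, "group") <- setNames(grp, names(out))
  out
}

#' Screen candidates against a current model
#'
#' Fits the current model augmented by each candidate separately and
#' reports the OFV drop. Extended models start at the current estimates
#' with the new effect at its null value, so a successful fit can never
#' report a negative drop beyond optimizer noise.
#'
#' @param dataset a `population_dataset`
#' @param current_fit the incumbent `vanc_fit`
#' @param candidates named list of [cov_spec] candidates
#' @param config a [search_config()]
#' @return data.frame with `candidate`, `ofv`, `dofv`
#' @export
screen_candidates <- function(dataset, current_fit, candidates,
                              config = search_config()) {
  rows <- lapply(names(candidates), function(nm) {
    f <- fit_quiet(dataset, add_cl_cov(current_fit$spec, candidates[[nm]]),
                   config$estimation)
    data.frame(candidate = nm,
               ofv = if (is.null(f)) NA_real_ else f$ofv,
               dofv = if (is.null(f)) NA_real_ else current_fit$ofv - f$ofv,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Step 3: forward inclusion / backward elimination
#'
#' Forward pass: repeatedly add the candidate with the largest significant
#' OFV drop (> `forward_dofv`), removing candidates from the same collinear
#' group; ties break deterministically by candidate list order. Backward
#' pass: among the covariates added here, remove any whose exclusion raises
#' the OFV by at most `backward_dofv`; a removed covariate cannot re-enter.
#'
#' @param dataset a `population_dataset`
#' @param current_fit incumbent `vanc_fit` (e.g. from step 2)
#' @param candidates named candidate list, default [default_candidates()]
#' @param config a [search_config()]
#' @return list with `forward` and `backward` decision tables, the set of
#'   covariates `added`, and the final `fit`/`spec`
#' @export
step3_forward_backward <- function(dataset, current_fit, candidates = NULL,
                                   config = search_config()) {
  if (is.null(candidates))
    candidates <- default_candidates(dataset, current_fit$spec)
  groups <- attr(candidates, "group") %||%
    setNames(names(candidates), names(candidates))
  cur <- current_fit
  added <- character(0)
  fwd_rows <- list()

  while (length(candidates) > 0) {
    scr <- screen_candidates(dataset, cur, candidates, config)
    scr$iteration <- length(fwd_rows) + 1L
    fwd_rows[[length(fwd_rows) + 1]] <- scr
    ok <- which(!is.na(scr$dofv) & scr$dofv > config$forward_dofv)
    if (length(ok) == 0) break
    best <- ok[which.max(scr$dofv[ok])]
    # deterministic tie-break: first candidate in list order among maxima
    best <- ok[which(scr$dofv[ok] == max(scr$dofv[ok]))[1]]
    nm <- scr$candidate[best]
    cur <- fit_quiet(dataset, add_cl_cov(cur$spec, candidates[[nm]]),
                     config$estimation)
    added <- c(added, nm)
    drop_grp <- groups[nm]
    candidates <- candidates[groups[names(candidates)] != drop_grp]
  }
  forward <- if (length(fwd_rows)) do.call(rbind, fwd_rows) else
    data.frame(candidate = character(0), ofv = numeric(0),
               dofv = numeric(0), iteration = integer(0))

  bwd_rows <- list()
  repeat {
    if (length(added) == 0) break
    incr <- vapply(added, function(nm) {
      f <- fit_quiet(dataset, drop_cl_cov(cur$spec, nm),
                     config$estimation)
      if (is.null(f)) Inf else f$ofv - cur$ofv
    }, numeric(1))
    bwd_rows[[length(bwd_rows) + 1]] <- data.frame(
      candidate = added, ofv_increase = incr, stringsAsFactors = FALSE)
    weakest <- which.min(incr)
    if (incr[weakest] > config$backward_dofv) break
    nm <- added[weakest]
    cur <- fit_quiet(dataset, drop_cl_cov(cur$spec, nm),
                     config$estimation)
    added <- setdiff(added, nm)
  }
  backward <- if (length(bwd_rows)) do.call(rbind, bwd_rows) else
    data.frame(candidate = character(0), ofv_increase = numeric(0))

  list(forward = forward, backward = backward, added = added,
       fit = cur, spec = cur$spec)
}

#' Step 4: time-varying covariate refinement
#'
#' For each continuous clearance covariate that actually varies within
#' subjects, replaces the static form with (a) the baseline /
#' change-from-baseline decomposition and (b) the random-slope variant
#' (with the slope's random effect held at zero: a second random-effect
#' dimension is not identifiable from peak/trough sampling). A variant is
#' retained only when the OFV improves by more than `tv_dofv`; covariates
#' constant within all subjects are skipped with a note.
#'
#' @param dataset a `population_dataset`
#' @param current_fit incumbent `vanc_fit`
#' @param config a [search_config()]
#' @return list with per-covariate `table`, `notes`, per-subject
#'   `decomposition` (baseline and mean delta), and the final `fit`/`spec`
#' @export
step4_time_varying <- function(dataset, current_fit,
                               config = search_config()) {
  cur <- current_fit
  notes <- character(0)
  tabs <- list()
  decomp <- list()
  cont_in_model <- intersect(cl_cov_names(cur$spec), .cont_cov_cols)
  for (cc in cont_in_model) {
    varies <- any(vapply(dataset$subjects, function(s) {
      v <- s$covariates[[cc]]
      !is.null(v) && length(unique(v)) > 1
    }, logical(1)))
    if (!varies) {
      notes <- c(notes, paste0(cc, ": constant within all subjects; ",
                               "time-varying variants skipped"))
      next
    }
    bc <- baseline_covariates(dataset)
    refb <- median(bc[[cc]], na.rm = TRUE)
    decomp[[cc]] <- do.call(rbind, lapply(dataset$subjects, function(s) {
      v <- s$covariates[[cc]]
      data.frame(id = s$id, covariate = cc, baseline = v[1],
                 mean_delta = mean(v - v[1]), stringsAsFactors = FALSE)
    }))
    sp12 <- add_cl_cov(drop_cl_cov(cur$spec, cc),
                       cov_tv_baseline_delta(cc, ref = refb))
    sp13 <- add_cl_cov(drop_cl_cov(cur$spec, cc),
                       cov_tv_random(cc, ref = refb, slope = 0))
    f12 <- fit_quiet(dataset, sp12, config$estimation)
    f13 <- fit_quiet(dataset, sp13, config$estimation)
    tab <- rbind(fit_row(paste0(cc, " baseline/delta"), f12, config),
                 fit_row(paste0(cc, " random slope"), f13, config))
    tab$dofv <- cur$ofv - tab$ofv
    tabs[[cc]] <- tab
    best <- which.max(ifelse(is.na(tab$dofv), -Inf, tab$dofv))
    if (length(best) == 1 && !is.na(tab$dofv[best]) &&
        tab$dofv[best] > config$tv_dofv) {
      cur <- list(f12, f13)[[best]]
      notes <- c(notes, paste0(cc, ": time-varying variant retained (",
                               tab$model[best], ")"))
    } else {
      notes <- c(notes, paste0(cc, ": no time-varying improvement; ",
                               "static form kept"))
    }
  }
  list(table = if (length(tabs)) do.call(rbind, tabs) else NULL,
       notes = notes,
       decomposition = if (length(decomp)) do.call(rbind, decomp) else NULL,
       fit = cur, spec = cur$spec)
}

#' Run the full four-step covariate search
#'
#' @param dataset a `population_dataset`
#' @param config a [search_config()]
#' @return a `search_report`: the per-step fragments, the audit log of
#'   decisions, and the final `fit`/`spec`
#' @export
run_covariate_search <- function(dataset, config = search_config()) {
  log <- character(0)
  s1 <- step1_size_models(dataset, config)
  log <- c(log, paste0("step1: selected ", s1$best))
  s2 <- step2_renal_models(dataset, s1, config)
  log <- c(log, if (s2$included)
    paste0("step2: Scr included (", s2$form, " form)")
    else "step2: Scr not included")
  s3 <- step3_forward_backward(dataset, s2$fit, config = config)
  log <- c(log, paste0("step3: added {",
                       paste(s3$added, collapse = ", "), "}"))
  s4 <- step4_time_varying(dataset, s3$fit, config)
  log <- c(log, s4$notes)
  structure(list(step1 = s1, step2 = s2, step3 = s3, step4 = s4,
                 log = log, fit = s4$fit, spec = s4$spec),
            class = "search_report")
}

#' @export
print.search_report <- function(x, ...) {
  cat("<search_report>\n")
  for (line in x$log) cat(" -", line, "\n")
  cat(sprintf("final clearance covariates: {%s}\n",
              paste(cl_cov_names(x$spec), collapse = ", ")))
  invisible(x)
}
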