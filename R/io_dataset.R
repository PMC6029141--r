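#' @name dataset
#' @title Longitudinal event-table datasets
#'
#' @description
#' A `population_dataset` holds one `subject_record` per neonate. Each
#' subject carries:
#' * `covariates`: time-ordered covariate states (columns `time`, `WT`,
#'   `SCR`, `GA`, `PNA`, `PMA`, `SEX`, plus optional labs `BUN`, `ALB`,
#'   `AST`, `ALT` and co-medication flags `CEF`, `MER`, `GEN`, `FUR`,
#'   `IBU`, `DEX`), carried forward in time within the subject;
#' * `doses`: constant-rate infusion events (`start`, `amount`, `duration`
#'   in hours/mg, rate = amount/duration);
#' * `observations`: concentrations (`time`, `value`, `kind` in
#'   trough/peak, `below_detection` for values under the 1 mg/L assay
#'   detection limit, `below_calibration` under the 3 mg/L calibration
#'   floor; flagged values are retained, not dropped).
#'
#' Times are hours since the subject's first dose. `SEX` is coded 0 = male,
#' 1 = female; co-medication flags are 0/1.
NULL

.cont_cov_cols <- c("WT", "SCR", "GA", "PNA", "PMA", "BUN", "ALB", "AST", "ALT")
.cat_cov_cols <- c("SEX", "CEF", "MER", "GEN", "FUR", "IBU", "DEX")
.cov_cols <- c(.cont_cov_cols, .cat_cov_cols)
.required_cols <- c("ID", "TIME", "EVID", "AMT", "DUR", "DV", "MDV",
                    "WT", "SCR", "GA", "PNA", "PMA", "SEX")

#' Construct a subject record
#'
#' @param id subject identifier
#' @param covariates covariate-state data.frame (see [dataset])
#' @param doses dose-event data.frame
#' @param observations observation data.frame
#' @return a `subject_record`
#' @export
subject_record <- function(id, covariates, doses, observations) {
  s <- structure(list(id = id, covariates = covariates, doses = doses,
                      observations = observations),
                 class = "subject_record")
  validate_subject(s)
  s
}

validate_subject <- function(s) {
  cv <- s$covariates
  if (any(cv$WT <= 0, na.rm = TRUE) || any(cv$SCR <= 0, na.rm = TRUE))
    stop_domain(paste0("subject ", s$id, ": WT and SCR must be positive"))
  if (any(abs(cv$PMA - (cv$GA + cv$PNA / 7)) > 0.2, na.rm = TRUE))
    stop_domain(paste0("subject ", s$id,
                       ": PMA inconsistent with GA + PNA/7 (tolerance 0.2 wk)"))
  if (nrow(s$doses) > 0 &&
      (any(s$doses$amount <= 0) || any(s$doses$duration <= 0)))
    stop_domain(paste0("subject ", s$id,
                       ": dose amounts and durations must be positive"))
  if (is.unsorted(s$doses$start) || is.unsorted(s$observations$time) ||
      is.unsorted(cv$time))
    stop_domain(paste0("subject ", s$id, ": times must be non-decreasing"))
  if (nrow(s$observations) > 0) {
    if (nrow(s$doses) == 0 ||
        min(s$observations$time) < min(s$doses$start))
      stop_domain(paste0("subject ", s$id,
                         ": every observation must be preceded by a dose"))
    bad <- !s$observations$below_detection & s$observations$value <= 0
    if (any(bad))
      stop_domain(paste0("subject ", s$id,
                         ": non-BLQ observations must be positive"))
  }
  invisible(s)
}

#' Construct a population dataset
#'
#' @param subjects list of [subject_record()] objects
#' @param provenance free-form metadata list (generator seed or file path,
#'   creation parameters)
#' @return a `population_dataset`
#' @export
population_dataset <- function(subjects, provenance = list()) {
  ids <- vapply(subjects, function(s) as.character(s$id), character(1))
  if (anyDuplicated(ids))
    stop_domain("subject ids must be unique")
  structure(list(subjects = subjects, provenance = provenance),
            class = "population_dataset")
}

#' @export
print.population_dataset <- function(x, ...) {
  nobs <- sum(vapply(x$subjects, function(s) nrow(s$observations), 0L))
  ndose <- sum(vapply(x$subjects, function(s) nrow(s$doses), 0L))
  cat(sprintf("<population_dataset> %d subjects, %d doses, %d observations\n",
              length(x$subjects), ndose, nobs))
  invisible(x)
}

n_observations <- function(ds)
  sum(vapply(ds$subjects, function(s) nrow(s$observations), 0L))

# ---- event table conversion ---------------------------------------------

.fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "" else sprintf("%.12g", v)
  }, character(1))
  out
}

#' Convert a dataset to a NONMEM-style event table
#'
#' One row per dose (`EVID = 1`, `MDV = 1`) or observation (`EVID = 0`,
#' `MDV = 0`), with covariates merged on by last-observation-carried-forward
#' within subject. `KIND` is 1 for troughs, 2 for peaks; `BLOD`/`BCAL` are
#' the assay-limit flags.
#'
#' @param dataset a `population_dataset`
#' @return a data.frame in event-table order
#' @export
as_event_table <- function(dataset) {
  rows <- lapply(dataset$subjects, function(s) {
    dn <- nrow(s$doses)
    on <- nrow(s$observations)
    df <- data.frame(
      ID = rep(s$id, dn + on),
      TIME = c(s$doses$start, s$observations$time),
      EVID = c(rep(1L, dn), rep(0L, on)),
      AMT = c(s$doses$amount, rep(NA_real_, on)),
      DUR = c(s$doses$duration, rep(NA_real_, on)),
      DV = c(rep(NA_real_, dn), s$observations$value),
      MDV = c(rep(1L, dn), rep(0L, on)),
      KIND = c(rep(NA_integer_, dn),
               ifelse(s$observations$kind == "peak", 2L, 1L)),
      BLOD = c(rep(NA_integer_, dn),
               as.integer(s$observations$below_detection)),
      BCAL = c(rep(NA_integer_, dn),
               as.integer(s$observations$below_calibration)),
      stringsAsFactors = FALSE
    )
    df <- df[order(df$TIME, -df$EVID), , drop = FALSE]
    for (cc in .cov_cols) {
      vals <- if (cc %in% names(s$covariates)) s$covariates[[cc]] else NA_real_
      df[[cc]] <- locf_at(s$covariates$time, vals, df$TIME)
    }
    df
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

locf_at <- function(ctime, cval, at) {
  if (length(ctime) == 0) return(rep(NA_real_, length(at)))
  idx <- findInterval(at, ctime)
  idx[idx < 1] <- 1L
  cval[idx]
}

#' Write a dataset as an event-table CSV
#'
#' Output is byte-stable for a given dataset; floating point values keep 12
#' significant digits. Flags are serialized as 0/1 columns.
#'
#' @param dataset a `population_dataset`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_dataset <- function(dataset, path) {
  tab <- as_event_table(dataset)
  chr <- as.data.frame(lapply(tab, function(col) {
    if (is.numeric(col)) .fmt_num(col) else as.character(col)
  }), stringsAsFactors = FALSE)
  names(chr) <- names(tab)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(chr), collapse = ","), con)
  if (nrow(chr) > 0) {
    lines <- do.call(paste, c(unname(as.list(chr)), list(sep = ",")))
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read an event-table CSV
#'
#' Expects the column dialect written by [write_dataset()]: `ID`, `TIME`,
#' `EVID`, `AMT`, `DUR`, `DV`, `MDV` plus the covariate columns. Rows are
#' partitioned into dose events (`EVID = 1`) and observations (`EVID = 0`,
#' `MDV = 0`); covariates are carried forward within subject. Missing
#' required columns raise a schema error naming the column; non-monotone
#' times within a subject raise a validation error.
#'
#' @param path CSV file path
#' @return a `population_dataset`
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) stop_domain(paste0("file not found: ", path))
  tab <- read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.required_cols, names(tab))
  if (length(missing_cols) > 0)
    stop_domain(paste0("schema error: missing column(s) ",
                       paste(missing_cols, collapse = ", ")))
  dataset_from_event_table(tab, provenance = list(source = path))
}

#' Build a dataset from an event-table data.frame
#'
#' @param tab event-table data.frame (see [read_dataset()])
#' @param provenance metadata list
#' @return a `population_dataset`
#' @export
dataset_from_event_table <- function(tab, provenance = list()) {
  req_cov <- c("WT", "SCR", "GA", "PNA", "PMA", "SEX")
  subjects <- lapply(split(tab, factor(tab$ID, levels = unique(tab$ID))),
                     function(st) {
    if (is.unsorted(st$TIME))
      stop_domain(paste0("validation error: TIME not non-decreasing for ",
                         "subject ", st$ID[1]))
    if (any(is.na(st[req_cov])))
      stop_domain(paste0("validation error: missing covariate values for ",
                         "subject ", st$ID[1]))
    drow <- st[st$EVID == 1, , drop = FALSE]
    orow <- st[st$EVID == 0 & st$MDV == 0, , drop = FALSE]
    doses <- data.frame(start = drow$TIME, amount = drow$AMT,
                        duration = drow$DUR)
    kind <- if ("KIND" %in% names(orow) && !all(is.na(orow$KIND))) {
      ifelse(orow$KIND == 2, "peak", "trough")
    } else {
      classify_kind(orow$TIME, doses)
    }
    obs <- data.frame(
      time = orow$TIME, value = orow$DV, kind = kind,
      below_detection = if ("BLOD" %in% names(orow) && !all(is.na(orow$BLOD)))
        orow$BLOD == 1 else orow$DV < 1,
      below_calibration = if ("BCAL" %in% names(orow) && !all(is.na(orow$BCAL)))
        orow$BCAL == 1 else orow$DV < 3,
      stringsAsFactors = FALSE
    )
    # keep the first row and every row whose covariate vector changes:
    # the minimal state sequence consistent with LOCF semantics
    present <- intersect(.cov_cols, names(st))
    cmat <- st[, present, drop = FALSE]
    changed <- TRUE
    if (nrow(cmat) > 1) {
      diffs <- cmat[-1, , drop = FALSE] != cmat[-nrow(cmat), , drop = FALSE]
      changed <- c(TRUE, rowSums(diffs, na.rm = TRUE) > 0)
    }
    covs <- cbind(data.frame(time = st$TIME[changed]),
                  cmat[changed, , drop = FALSE])
    rownames(covs) <- NULL
    subject_record(id = st$ID[1], covariates = covs, doses = doses,
                   observations = obs)
  })
  population_dataset(unname(subjects), provenance = provenance)
}

# fall-back observation typing when KIND is absent: a sample within 1.5 h
# of an infusion end is a peak, otherwise a trough
classify_kind <- function(times, doses) {
  vapply(times, function(t) {
    ends <- doses$start + doses$duration
    past <- ends[ends <= t]
    if (length(past) > 0 && (t - max(past)) <= 1.5) "peak" else "trough"
  }, character(1))
}

# ---- engine flattening ---------------------------------------------------

# Flattens a dataset into the offset arrays consumed by the C++ kernel plus
# a per-observation covariate frame (LOCF at observation times, with
# baseline columns B<COV> for the time-varying forms).
flatten_dataset <- function(ds) {
  subs <- ds$subjects
  nobs <- vapply(subs, function(s) nrow(s$observations), 0L)
  ndose <- vapply(subs, function(s) nrow(s$doses), 0L)
  obs_off <- c(0L, cumsum(nobs))
  dose_off <- c(0L, cumsum(ndose))

  covs_list <- lapply(subs, function(s) {
    ot <- s$observations$time
    row <- data.frame(row.names = seq_along(ot))
    for (cc in .cov_cols) {
      vals <- if (cc %in% names(s$covariates)) s$covariates[[cc]]
              else rep(NA_real_, nrow(s$covariates))
      row[[cc]] <- locf_at(s$covariates$time, vals, ot)
      if (cc %in% .cont_cov_cols) row[[paste0("B", cc)]] <- vals[1]
    }
    row
  })

  list(
    obs_off = obs_off,
    obs_time = unlist(lapply(subs, function(s) s$observations$time),
                      use.names = FALSE) %||% numeric(0),
    dv = unlist(lapply(subs, function(s) s$observations$value),
                use.names = FALSE) %||% numeric(0),
    dose_off = dose_off,
    dose_start = unlist(lapply(subs, function(s) s$doses$start),
                        use.names = FALSE) %||% numeric(0),
    dose_dur = unlist(lapply(subs, function(s) s$doses$duration),
                      use.names = FALSE) %||% numeric(0),
    dose_rate = unlist(lapply(subs, function(s) s$doses$amount / s$doses$duration),
                       use.names = FALSE) %||% numeric(0),
    covs = do.call(rbind, covs_list),
    ids = vapply(subs, function(s) as.character(s$id), character(1)),
    obs_id = rep(vapply(subs, function(s) as.character(s$id), character(1)),
                 nobs),
    n_obs = sum(nobs),
    n_subjects = length(subs)
  )
}

# per-subject baseline covariate frame (first covariate state), used for
# candidate-set medians and dosing scenarios
baseline_covariates <- function(ds) {
  rows <- lapply(ds$subjects, function(s) {
    out <- data.frame(ID = s$id)
    for (cc in .cov_cols) {
      out[[cc]] <- if (cc %in% names(s$covariates)) s$covariates[[cc]][1]
                   else NA_real_
    }
    out
  })
  do.call(rbind, rows)
}
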