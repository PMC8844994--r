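#' Postmenstrual age from gestational age and postnatal time
#'
#' PMA is the gestational age at birth plus the postnatal time elapsed,
#' both in days.
#'
#' @param gestational_age Gestational age at birth, days (>= 0).
#' @param postnatal_time Postnatal time, days (>= 0).
#' @return Postmenstrual age, days.
#' @export
compute_pma <- function(gestational_age, postnatal_time) {
  if (any(gestational_age < 0) || any(postnatal_time < 0)) {
    stop("gestational_age and postnatal_time must be non-negative")
  }
  gestational_age + postnatal_time
}

#' Construct a subject record
#'
#' A subject record holds demographics, dose events, concentration
#' observations and a time-stamped covariate series. Times are hours since
#' the subject's reference time (normally the first dose).
#'
#' @param subject_id Character id, unique within a cohort.
#' @param doses data.frame with columns `time` (h), `amount` (mg),
#'   `duration` (h) and optionally `occasion`.
#' @param obs data.frame with columns `time` (h), `value` (mg/L), `blq`
#'   (logical), `lloq` (mg/L) and optionally `occasion`.
#' @param cov Covariate series: data.frame with columns `time` (h), `wt`
#'   (kg), `scr` (umol/L), `pma` (days); `wt` and `scr` may contain `NA`
#'   before imputation. Optional logical columns `wt_imputed`,
#'   `scr_imputed`.
#' @param sex `"M"`, `"F"` or `NA`.
#' @param birth_weight kg (> 0) or `NA`.
#' @param gestational_age days (> 0) or `NA`.
#' @param truth Optional simulation truth: list with `eta_bsv` and a named
#'   vector `eta_bov` (by occasion).
#' @return A `subject_record` object.
#' @export
subject_record <- function(subject_id, doses, obs, cov,
                           sex = NA_character_, birth_weight = NA_real_,
                           gestational_age = NA_real_, truth = NULL) {
  doses <- as.data.frame(doses)
  obs <- as.data.frame(obs)
  cov <- as.data.frame(cov)
  if (nrow(doses) && (any(doses$time < 0) || is.unsorted(doses$time))) {
    stop("dose times must be non-negative and sorted")
  }
  if (nrow(doses) && (any(doses$amount <= 0) || any(doses$duration <= 0))) {
    stop("dose amount and infusion duration must be positive")
  }
  if (nrow(obs) && (any(obs$time < 0) || is.unsorted(obs$time))) {
    stop("observation times must be non-negative and sorted")
  }
  if (nrow(obs) && any(obs$value < 0, na.rm = TRUE)) {
    stop("observed concentrations must be non-negative")
  }
  if (!is.na(birth_weight) && birth_weight <= 0) stop("birth_weight must be positive")
  if (!is.na(gestational_age) && gestational_age <= 0) stop("gestational_age must be positive")
  if (!"occasion" %in% names(doses)) doses$occasion <- rep(1L, nrow(doses))
  if (!"occasion" %in% names(obs)) obs$occasion <- rep(1L, nrow(obs))
  if (!"wt_imputed" %in% names(cov)) cov$wt_imputed <- rep(FALSE, nrow(cov))
  if (!"scr_imputed" %in% names(cov)) cov$scr_imputed <- rep(FALSE, nrow(cov))
  structure(list(subject_id = as.character(subject_id), sex = sex,
                 birth_weight = birth_weight, gestational_age = gestational_age,
                 doses = doses, obs = obs, cov = cov, truth = truth),
            class = "subject_record")
}

#' Construct a cohort
#'
#' @param subjects List of [subject_record()] objects with unique ids.
#' @param log List of applied-rule records (provenance).
#' @return A `vanc_cohort` object.
#' @export
cohort <- function(subjects, log = list()) {
  ids <- vapply(subjects, function(s) s$subject_id, "")
  if (anyDuplicated(ids)) stop("subject ids must be unique")
  structure(list(subjects = stats::setNames(subjects, ids), log = log),
            class = "vanc_cohort")
}

#' @export
print.vanc_cohort <- function(x, ...) {
  nobs <- sum(vapply(x$subjects, function(s) nrow(s$obs), 0L))
  ndose <- sum(vapply(x$subjects, function(s) nrow(s$doses), 0L))
  cat(sprintf("cohort: %d subjects, %d dose events, %d observations, %d log entries\n",
              length(x$subjects), ndose, nobs, length(x$log)))
  invisible(x)
}

#' @export
length.vanc_cohort <- function(x) length(x$subjects)

.event_columns <- c("ID", "TIME_H", "EVID", "AMT_MG", "RATE_MG_H", "DV_MG_L",
                    "BLQ", "LLOQ", "WT_KG", "SCR_UMOL_L", "PMA_DAYS")

#' Parse an event-record table into a cohort
#'
#' Reads a NONMEM-style long table with one row per dose or observation.
#' Mandatory columns: `ID`, `TIME_H`, `EVID` (1 = dose, 0 = observation),
#' `AMT_MG`, `RATE_MG_H`, `DV_MG_L`, `BLQ`, `LLOQ`, `WT_KG`, `SCR_UMOL_L`,
#' `PMA_DAYS`. Optional: `OCC`, `DUR_H`, `SEX`, `BW_KG`, `GA_DAYS`.
#' Dose rows must carry `AMT_MG` and either `RATE_MG_H` or `DUR_H`
#' (duration = amount / rate, constant-rate assumption; a missing rate
#' falls back to `default_infusion_h`). Covariate values present on any
#' row become covariate-series entries at that row's time.
#'
#' @param table A data.frame or a path to a CSV file (UTF-8, header).
#' @param default_infusion_h Infusion duration used when a dose row has
#'   neither rate nor duration (default 1 h).
#' @return A `vanc_cohort`.
#' @export
parse_dataset <- function(table, default_infusion_h = 1) {
  df <- if (is.character(table)) {
    if (!file.exists(table)) stop("dataset file not found: ", table)
    utils::read.csv(table, stringsAsFactors = FALSE)
  } else as.data.frame(table)
  missing_cols <- setdiff(.event_columns, names(df))
  if (length(missing_cols)) {
    stop("format error: missing mandatory columns: ",
         paste(missing_cols, collapse = ", "))
  }
  if (any(df$TIME_H < 0, na.rm = TRUE)) stop("validation error: negative time")
  if (!all(df$EVID %in% c(0L, 1L))) stop("format error: EVID must be 0 or 1")
  subjects <- lapply(split(df, factor(df$ID, levels = unique(df$ID))), function(d) {
    d <- d[order(d$TIME_H, -d$EVID), , drop = FALSE]
    dd <- d[d$EVID == 1, , drop = FALSE]
    dur <- if ("DUR_H" %in% names(dd) && any(!is.na(dd$DUR_H))) {
      ifelse(!is.na(dd$DUR_H), dd$DUR_H, dd$AMT_MG / dd$RATE_MG_H)
    } else dd$AMT_MG / dd$RATE_MG_H
    dur[!is.finite(dur)] <- default_infusion_h
    doses <- data.frame(time = dd$TIME_H, amount = dd$AMT_MG, duration = dur)
    if ("OCC" %in% names(dd) && any(!is.na(dd$OCC))) doses$occasion <- as.integer(dd$OCC)
    od <- d[d$EVID == 0, , drop = FALSE]
    obs <- data.frame(time = od$TIME_H, value = od$DV_MG_L,
                      blq = as.logical(od$BLQ) %in% TRUE,
                      lloq = ifelse(is.na(od$LLOQ), 1, od$LLOQ))
    if ("OCC" %in% names(od) && any(!is.na(od$OCC))) obs$occasion <- as.integer(od$OCC)
    cov <- data.frame(time = d$TIME_H, wt = d$WT_KG, scr = d$SCR_UMOL_L,
                      pma = d$PMA_DAYS)
    cov <- cov[!duplicated(cov$time), , drop = FALSE]
    row.names(cov) <- NULL
    first <- function(col) if (col %in% names(d) && any(!is.na(d[[col]]))) d[[col]][!is.na(d[[col]])][1] else NA
    subject_record(d$ID[1], doses, obs, cov,
                   sex = as.character(first("SEX")),
                   birth_weight = as.numeric(first("BW_KG")),
                   gestational_age = as.numeric(first("GA_DAYS")))
  })
  cohort(unname(subjects), log = list(list(rule = "parse_dataset",
                                           n_subjects = length(subjects))))
}

#' Write a cohort to an event-record table
#'
#' Inverse of [parse_dataset()]: one row per dose or observation with the
#' documented column dictionary. Covariates are carried on every row by
#' exact-time lookup into the covariate series (NA when absent).
#'
#' @param x A `vanc_cohort`.
#' @param path Optional CSV output path; when `NULL` the data.frame is
#'   returned instead.
#' @return The event-record data.frame, invisibly when `path` is given.
#' @export
write_dataset <- function(x, path = NULL) {
  stopifnot(inherits(x, "vanc_cohort"))
  rows <- lapply(x$subjects, function(s) {
    lookup <- function(tt, col) {
      i <- match(tt, s$cov$time)
      ifelse(is.na(i), NA_real_, s$cov[[col]][i])
    }
    dd <- s$doses
    drows <- data.frame(ID = rep(s$subject_id, nrow(dd)), TIME_H = dd$time,
                        EVID = rep(1L, nrow(dd)), AMT_MG = dd$amount,
                        RATE_MG_H = dd$amount / dd$duration, DUR_H = dd$duration,
                        DV_MG_L = NA_real_, BLQ = NA,
                        LLOQ = NA_real_, WT_KG = lookup(dd$time, "wt"),
                        SCR_UMOL_L = lookup(dd$time, "scr"),
                        PMA_DAYS = lookup(dd$time, "pma"),
                        OCC = dd$occasion)
    oo <- s$obs
    orows <- data.frame(ID = rep(s$subject_id, nrow(oo)), TIME_H = oo$time,
                        EVID = rep(0L, nrow(oo)), AMT_MG = NA_real_,
                        RATE_MG_H = NA_real_, DUR_H = NA_real_,
                        DV_MG_L = oo$value, BLQ = oo$blq, LLOQ = oo$lloq,
                        WT_KG = lookup(oo$time, "wt"),
                        SCR_UMOL_L = lookup(oo$time, "scr"),
                        PMA_DAYS = lookup(oo$time, "pma"),
                        OCC = oo$occasion)
    out <- rbind(drows, orows)
    out$SEX <- s$sex; out$BW_KG <- s$birth_weight; out$GA_DAYS <- s$gestational_age
    out[order(out$TIME_H, -out$EVID), , drop = FALSE]
  })
  df <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(path)) return(df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

# covariates at a given time, from the (imputed) covariate series:
# exact match preferred, otherwise nearest in time (ties -> earlier)
covariates_at <- function(subject, time) {
  cv <- subject$cov
  if (!nrow(cv)) stop("subject ", subject$subject_id, " has no covariate series")
  d <- abs(cv$time - time)
  i <- which(d == min(d))[1]
  pma <- if (!is.na(cv$pma[i])) cv$pma[i] + (time - cv$time[i]) / 24 else NA_real_
  list(wt = cv$wt[i], scr = cv$scr[i], pma = pma)
}
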