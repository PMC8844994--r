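# Preprocessing rules applied to EHR-style event records before modelling:
# observation-window and during-infusion filters, early-onset subject
# exclusion, covariate imputation and LLOQ handling. All operations are
# idempotent and log what they removed or changed.

#' Apply cohort exclusion rules
#'
#' Three rules, in order: (1) remove observations taken more than
#' `post_infusion_cutoff` days after the start of the subject's last
#' infusion; (2) remove observations drawn during an infusion (open
#' interval: a sample exactly at the end of the infusion is a peak and is
#' retained); (3) remove subjects whose first dose was given before
#' `pna_cutoff` days of postnatal age. Postnatal age is derived from the
#' covariate series as PMA minus gestational age at the first dose.
#'
#' @param x A `vanc_cohort`.
#' @param pna_cutoff Days; subjects starting vancomycin earlier are
#'   excluded (default 7).
#' @param post_infusion_cutoff Days after the start of the last infusion
#'   beyond which observations are dropped (default 7).
#' @return The filtered cohort; the exclusion report is appended to the
#'   cohort log (`rule = "apply_exclusions"`).
#' @export
apply_exclusions <- function(x, pna_cutoff = 7, post_infusion_cutoff = 7) {
  stopifnot(inherits(x, "vanc_cohort"))
  n_late <- 0L; n_during <- 0L
  subjects <- lapply(x$subjects, function(s) {
    if (!nrow(s$doses)) return(s)
    last_start <- max(s$doses$time)
    keep_late <- s$obs$time <= last_start + post_infusion_cutoff * 24
    n_late <<- n_late + sum(!keep_late)
    o <- s$obs[keep_late, , drop = FALSE]
    during <- vapply(o$time, function(tt) {
      any(tt > s$doses$time & tt < s$doses$time + s$doses$duration)
    }, logical(1))
    n_during <<- n_during + sum(during)
    s$obs <- o[!during, , drop = FALSE]
    row.names(s$obs) <- NULL
    s
  })
  pna_first <- vapply(subjects, function(s) {
    if (!nrow(s$doses)) return(NA_real_)
    cv <- covariates_at(s, min(s$doses$time))
    ga <- if (!is.na(s$gestational_age)) s$gestational_age else NA_real_
    if (is.na(cv$pma) || is.na(ga)) NA_real_ else cv$pma - ga
  }, 0)
  early <- !is.na(pna_first) & pna_first < pna_cutoff
  report <- list(rule = "apply_exclusions",
                 n_obs_late = n_late, n_obs_during_infusion = n_during,
                 n_subjects_early_onset = sum(early),
                 excluded_subjects = names(subjects)[early])
  cohort(unname(subjects[!early]), log = c(x$log, list(report)))
}

# piecewise-linear interpolation with linear extrapolation on the end
# segments; a single support point gives a constant
.interp_linear <- function(xs, ys, xout) {
  if (length(xs) == 1) return(rep(ys, length(xout)))
  o <- order(xs); xs <- xs[o]; ys <- ys[o]
  out <- stats::approx(xs, ys, xout = xout, rule = 1)$y
  n <- length(xs)
  lo <- xout < xs[1]
  hi <- xout > xs[n]
  if (any(lo)) out[lo] <- ys[1] + (ys[2] - ys[1]) / (xs[2] - xs[1]) * (xout[lo] - xs[1])
  if (any(hi)) out[hi] <- ys[n] + (ys[n] - ys[n - 1]) / (xs[n] - xs[n - 1]) * (xout[hi] - xs[n])
  out
}

# nearest-in-time lookup; equidistant ties take the earlier value
.nearest <- function(xs, ys, xout) {
  o <- order(xs); xs <- xs[o]; ys <- ys[o]
  vapply(xout, function(x) {
    d <- abs(xs - x)
    ys[which(d == min(d))[1]]
  }, 0)
}

#' Impute the covariate series at every event time
#'
#' Serum creatinine is imputed as the nearest available value in time
#' (equidistant ties resolve to the earlier value); body weight is linearly
#' interpolated, and linearly extrapolated on the end segments (constant if
#' only one value exists). PMA is propagated from any anchored value by
#' elapsed time. Observed values are left bit-identical and flagged as not
#' imputed.
#'
#' @param x A `vanc_cohort`.
#' @return Cohort whose subjects carry a complete covariate series at every
#'   dose and observation time, with `wt_imputed` / `scr_imputed` flags.
#' @export
impute_covariates <- function(x) {
  stopifnot(inherits(x, "vanc_cohort"))
  subjects <- lapply(x$subjects, function(s) {
    cv <- s$cov
    # previously imputed entries are not measurements: idempotence
    wt_flag <- if (is.null(cv$wt_imputed)) rep(FALSE, nrow(cv)) else cv$wt_imputed
    scr_flag <- if (is.null(cv$scr_imputed)) rep(FALSE, nrow(cv)) else cv$scr_imputed
    wt_ok <- !is.na(cv$wt) & !(wt_flag %in% TRUE)
    scr_ok <- !is.na(cv$scr) & !(scr_flag %in% TRUE)
    wt_known <- cv[wt_ok, c("time", "wt")]
    scr_known <- cv[scr_ok, c("time", "scr")]
    if (!nrow(wt_known)) stop("validation error: subject ", s$subject_id,
                              " has no body-weight value")
    if (!nrow(scr_known)) stop("validation error: subject ", s$subject_id,
                               " has no serum-creatinine value")
    # de-duplicate repeated identical measurements at a time point
    wt_known <- wt_known[!duplicated(wt_known$time), , drop = FALSE]
    scr_known <- scr_known[!duplicated(scr_known$time), , drop = FALSE]
    times <- sort(unique(c(s$doses$time, s$obs$time, cv$time)))
    pma_anchor <- cv[!is.na(cv$pma), c("time", "pma")]
    pma <- if (nrow(pma_anchor)) {
      pma_anchor$pma[1] + (times - pma_anchor$time[1]) / 24
    } else rep(NA_real_, length(times))
    wt <- .interp_linear(wt_known$time, wt_known$wt, times)
    scr <- .nearest(scr_known$time, scr_known$scr, times)
    wt_obs <- match(times, wt_known$time)
    scr_obs <- match(times, scr_known$time)
    wt[!is.na(wt_obs)] <- wt_known$wt[wt_obs[!is.na(wt_obs)]]
    scr[!is.na(scr_obs)] <- scr_known$scr[scr_obs[!is.na(scr_obs)]]
    s$cov <- data.frame(time = times, wt = wt, scr = scr, pma = pma,
                        wt_imputed = is.na(wt_obs), scr_imputed = is.na(scr_obs))
    s
  })
  cohort(unname(subjects), log = c(x$log, list(list(rule = "impute_covariates"))))
}

#' Apply lower-limit-of-quantification rules
#'
#' Serum creatinine values below `scr_lloq` are replaced by `scr_lloq / 2`
#' (15 umol/L becomes 7.5 umol/L); values exactly at the limit are
#' unchanged. Vancomycin observations below `vcs_lloq` are flagged `blq`
#' and their value is set to the LLOQ placeholder (the record is kept and
#' enters the likelihood as a censored term, never as a measurement).
#'
#' @param x A `vanc_cohort`.
#' @param scr_lloq Serum-creatinine LLOQ, umol/L (default 15).
#' @param vcs_lloq Vancomycin LLOQ, mg/L (default 1).
#' @return The transformed cohort with a log entry of the counts.
#' @export
apply_lloq_rules <- function(x, scr_lloq = 15, vcs_lloq = 1) {
  stopifnot(inherits(x, "vanc_cohort"))
  n_scr <- 0L; n_blq <- 0L
  subjects <- lapply(x$subjects, function(s) {
    low <- !is.na(s$cov$scr) & s$cov$scr < scr_lloq
    n_scr <<- n_scr + sum(low)
    s$cov$scr[low] <- scr_lloq / 2
    if (nrow(s$obs)) {
      cens <- !s$obs$blq & s$obs$value < vcs_lloq
      n_blq <<- n_blq + sum(cens)
      s$obs$blq[cens] <- TRUE
      s$obs$lloq[cens] <- vcs_lloq
      s$obs$value[cens] <- vcs_lloq
    }
    s
  })
  cohort(unname(subjects),
         log = c(x$log, list(list(rule = "apply_lloq_rules",
                                  n_scr_replaced = n_scr, n_blq_flagged = n_blq))))
}

#' Assign dosing occasions by inter-dose gaps
#'
#' Consecutive doses separated by at most `gap_threshold` days share an
#' occasion; a larger gap starts a new occasion (the threshold itself is
#' inclusive). Observations inherit the occasion of the most recent dose at
#' or before their time (observations before the first dose join occasion 1).
#'
#' @param x A `vanc_cohort`.
#' @param gap_threshold Days (default 7, mirroring the observation window).
#' @return Cohort with `occasion` columns filled on doses and observations.
#' @export
assign_occasions <- function(x, gap_threshold = 7) {
  stopifnot(inherits(x, "vanc_cohort"))
  subjects <- lapply(x$subjects, function(s) {
    if (!nrow(s$doses)) return(s)
    gaps <- diff(s$doses$time)
    s$doses$occasion <- as.integer(cumsum(c(1, gaps > gap_threshold * 24)))
    if (nrow(s$obs)) {
      idx <- findInterval(s$obs$time, s$doses$time)
      idx[idx == 0] <- 1L
      s$obs$occasion <- s$doses$occasion[idx]
    }
    s
  })
  cohort(unname(subjects), log = c(x$log, list(list(rule = "assign_occasions",
                                                    gap_threshold_days = gap_threshold))))
}

#' Full preprocessing pipeline
#'
#' Applies, in order: [apply_exclusions()], [impute_covariates()],
#' [apply_lloq_rules()] and [assign_occasions()].
#'
#' @param x A `vanc_cohort` (e.g. from [parse_dataset()]).
#' @param pna_cutoff,post_infusion_cutoff See [apply_exclusions()].
#' @param scr_lloq,vcs_lloq See [apply_lloq_rules()].
#' @param gap_threshold See [assign_occasions()].
#' @return The preprocessed cohort with a full provenance log.
#' @export
preprocess_cohort <- function(x, pna_cutoff = 7, post_infusion_cutoff = 7,
                              scr_lloq = 15, vcs_lloq = 1, gap_threshold = 7) {
  x <- apply_exclusions(x, pna_cutoff, post_infusion_cutoff)
  x <- impute_covariates(x)
  x <- apply_lloq_rules(x, scr_lloq, vcs_lloq)
  assign_occasions(x, gap_threshold)
}
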