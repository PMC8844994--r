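# Synthetic-cohort generator calibrated to the demographics of the study
# population (preterm-dominated NICU neonates on intravenous vancomycin),
# plus simulation of concentration observations from the model. Together
# these make every other module testable without any patient data.

# moment-matched log-normal sigma: IQR = 2 * median * sinh(z75 * sigma)
.lnorm_sigma <- function(median, iqr) asinh(iqr / (2 * median)) / stats::qnorm(0.75)

# truncated draws via inverse-CDF so the configured range is respected
.rtrunc_norm <- function(n, mean, sd, lo, hi) {
  p <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(p, mean, sd)
}
.rtrunc_lnorm <- function(n, meanlog, sdlog, lo, hi) {
  p <- stats::runif(n, stats::plnorm(lo, meanlog, sdlog),
                    stats::plnorm(hi, meanlog, sdlog))
  stats::qlnorm(p, meanlog, sdlog)
}

#' Demographics configuration for the synthetic cohort
#'
#' Marginal summaries (median, IQR, range) of the emulated population:
#' a NICU cohort dominated by preterm neonates. Distribution families are
#' a documented choice: truncated normal for gestational age, truncated
#' log-normal (moment-matched to median and IQR) for the skewed positive
#' quantities. Defaults:
#' gestational age 30.1 (IQR 6.9, range 24.1-41.3) weeks; postnatal age at
#' first dose 17 (14, 7-114) days; birth weight 1.32 (0.89, 0.44-4.14) kg;
#' serum creatinine 42 (34, 15-252) umol/L; dose 14 (3, 5-31) mg/kg.
#'
#' @param ga_weeks,pna_days,bw_kg,scr,dose_per_kg Lists with `median`,
#'   `iqr`, `min`, `max`.
#' @param ga_bw_corr Gaussian-copula correlation between gestational age
#'   and birth weight (default 0.7; an assumption, the true joint
#'   structure is unreported).
#' @param growth_frac_per_day Postnatal weight gain as a fraction of birth
#'   weight per day (default 0.015).
#' @param n_doses Doses per course (default 8).
#' @param interval_rule PMA (weeks) thresholds mapping to dosing intervals:
#'   `< 30 wk` q12h, `30-37 wk` q8h, `>= 37 wk` q6h.
#' @param sampling Default sampling design: one trough immediately before
#'   dose `trough_before_dose` and one peak at the end of the infusion of
#'   dose `peak_after_dose` (the guideline's "1 trough + preferably
#'   1 peak").
#' @return A `demographics_config` object.
#' @export
demographics_config <- function(
    ga_weeks = list(median = 30.1, iqr = 6.9, min = 24.1, max = 41.3),
    pna_days = list(median = 17, iqr = 14, min = 7, max = 114),
    bw_kg = list(median = 1.32, iqr = 0.89, min = 0.44, max = 4.14),
    scr = list(median = 42, iqr = 34, min = 15, max = 252),
    dose_per_kg = list(median = 14, iqr = 3, min = 5, max = 31),
    ga_bw_corr = 0.7, growth_frac_per_day = 0.015, n_doses = 8,
    interval_rule = list(pma_weeks = c(30, 37), intervals = c(12, 8, 6)),
    sampling = list(trough_before_dose = 4, peak_after_dose = 4)) {
  for (d in list(ga_weeks, pna_days, bw_kg, scr, dose_per_kg)) {
    if (!(d$min <= d$median && d$median <= d$max)) {
      stop("infeasible demographics config: range must contain the median")
    }
    if (d$iqr <= 0 || d$min <= 0) stop("demographics summaries must be positive")
  }
  structure(list(ga_weeks = ga_weeks, pna_days = pna_days, bw_kg = bw_kg,
                 scr = scr, dose_per_kg = dose_per_kg,
                 ga_bw_corr = ga_bw_corr,
                 growth_frac_per_day = growth_frac_per_day,
                 n_doses = n_doses, interval_rule = interval_rule,
                 sampling = sampling),
            class = "demographics_config")
}

#' Generate a synthetic cohort (doses and covariates, no observations)
#'
#' Draws demographics from the configured truncated families (gestational
#' age and birth weight joined by a Gaussian copula), builds a q6-q12h
#' course of about 14 mg/kg doses (interval by PMA at first dose), a
#' linear-in-time weight trajectory, and per-subject random effects from
#' the model's BSV/BOV distributions, recorded as simulation truth.
#'
#' @param n Number of subjects (>= 1).
#' @param cfg A [demographics_config()].
#' @param pop A [pop_params()] (source of the random-effect variances).
#' @param seed Integer seed.
#' @return A `vanc_cohort`; each subject carries `truth` (`eta_bsv`,
#'   `eta_bov` named by occasion) and a complete covariate series at all
#'   dose times.
#' @export
generate_cohort <- function(n, cfg = demographics_config(), pop = pop_params(),
                            seed = 1L) {
  stopifnot(n >= 1, inherits(cfg, "demographics_config"),
            inherits(pop, "pop_params"))
  with_seed(seed, {
    # GA (truncated normal) and birth weight (truncated log-normal) share a
    # Gaussian copula with the configured rank-level correlation
    g <- cfg$ga_weeks
    sd_ga <- g$iqr / (2 * stats::qnorm(0.75))
    z1 <- stats::rnorm(n)
    z2 <- cfg$ga_bw_corr * z1 + sqrt(1 - cfg$ga_bw_corr^2) * stats::rnorm(n)
    u1 <- stats::pnorm(z1); u2 <- stats::pnorm(z2)
    p_lo <- stats::pnorm(g$min, g$median, sd_ga)
    p_hi <- stats::pnorm(g$max, g$median, sd_ga)
    ga_wk <- stats::qnorm(p_lo + u1 * (p_hi - p_lo), g$median, sd_ga)
    b <- cfg$bw_kg
    mul <- log(b$median); sdl <- .lnorm_sigma(b$median, b$iqr)
    q_lo <- stats::plnorm(b$min, mul, sdl); q_hi <- stats::plnorm(b$max, mul, sdl)
    bw <- stats::qlnorm(q_lo + u2 * (q_hi - q_lo), mul, sdl)
    p <- cfg$pna_days
    pna <- .rtrunc_lnorm(n, log(p$median), .lnorm_sigma(p$median, p$iqr),
                         p$min, p$max)
    s <- cfg$scr
    scr <- .rtrunc_lnorm(n, log(s$median), .lnorm_sigma(s$median, s$iqr),
                         s$min, s$max)
    d <- cfg$dose_per_kg
    mgkg <- .rtrunc_lnorm(n, log(d$median), .lnorm_sigma(d$median, d$iqr),
                          d$min, d$max)
    subjects <- lapply(seq_len(n), function(i) {
      ga_d <- ga_wk[i] * 7
      pma0 <- compute_pma(ga_d, pna[i])
      wt0 <- min(max(bw[i] * (1 + cfg$growth_frac_per_day * pna[i]), 0.4), 7.5)
      pma_wk <- pma0 / 7
      br <- cfg$interval_rule$pma_weeks
      tau <- cfg$interval_rule$intervals[findInterval(pma_wk, br) + 1]
      dose_mg <- round(mgkg[i] * wt0, 1)
      times <- (seq_len(cfg$n_doses) - 1) * tau
      doses <- data.frame(time = times, amount = dose_mg, duration = 1,
                          occasion = 1L)
      wt_t <- wt0 * (1 + cfg$growth_frac_per_day * times / 24)
      cov <- data.frame(time = times, wt = wt_t, scr = scr[i],
                        pma = pma0 + times / 24)
      truth <- list(eta_bsv = stats::rnorm(1, 0, sqrt(pop$omega2_bsv)),
                    eta_bov = c("1" = stats::rnorm(1, 0, sqrt(pop$omega2_bov))))
      subject_record(sprintf("SIM%04d", i),
                     doses = doses,
                     obs = data.frame(time = numeric(0), value = numeric(0),
                                      blq = logical(0), lloq = numeric(0),
                                      occasion = integer(0)),
                     cov = cov,
                     sex = sample(c("M", "F"), 1, prob = c(0.541, 0.459)),
                     birth_weight = bw[i], gestational_age = ga_d,
                     truth = truth)
    })
    cohort(subjects, log = list(list(rule = "generate_cohort", n = n, seed = seed)))
  })
}

#' Simulate concentration observations from the model
#'
#' Adds observations at the configured trough/peak times: the model
#' prediction at each subject's true random effects plus combined
#' proportional-additive residual error. Values below the LLOQ are flagged
#' `blq` and stored at the LLOQ placeholder. Troughs are drawn 0.05 h
#' before the target dose; peaks exactly at the end of its infusion.
#'
#' @param x A `vanc_cohort` from [generate_cohort()] (doses, covariates
#'   and truth present).
#' @param pop A [pop_params()] object.
#' @param design List with `trough_before_dose` and `peak_after_dose`
#'   (integer dose indices, vectors allowed; `NULL` drops that sample
#'   type).
#' @param seed Integer seed (residual noise).
#' @param lloq Censoring limit, mg/L (default 1).
#' @return The cohort with observations filled in; covariate series
#'   extended to the observation times.
#' @export
simulate_observations <- function(x, pop = pop_params(),
                                  design = list(trough_before_dose = 4,
                                                peak_after_dose = 4),
                                  seed = 1L, lloq = 1) {
  stopifnot(inherits(x, "vanc_cohort"))
  subjects <- with_seed(seed, lapply(x$subjects, function(s) {
    if (is.null(s$truth)) stop("subject ", s$subject_id, " has no simulation truth")
    nd <- nrow(s$doses)
    t_tr <- s$doses$time[pmin(design$trough_before_dose, nd)] - 0.05
    t_pk <- s$doses$time[pmin(design$peak_after_dose, nd)] +
      s$doses$duration[pmin(design$peak_after_dose, nd)]
    times <- sort(unique(c(t_tr, t_pk)))
    times <- times[times >= 0]
    idx <- findInterval(times, s$doses$time); idx[idx == 0] <- 1L
    occ <- s$doses$occasion[idx]
    obs <- data.frame(time = times, value = NA_real_, blq = FALSE,
                      lloq = lloq, occasion = occ)
    s$obs <- obs
    # extend the covariate series to the sampling times
    new_t <- setdiff(times, s$cov$time)
    if (length(new_t)) {
      wt0 <- s$cov$wt[1]
      g <- (s$cov$wt[nrow(s$cov)] / wt0 - 1) /
        max(s$cov$time[nrow(s$cov)] - s$cov$time[1], 1e-9)
      add <- data.frame(time = new_t,
                        wt = wt0 * (1 + g * (new_t - s$cov$time[1])),
                        scr = s$cov$scr[1],
                        pma = s$cov$pma[1] + (new_t - s$cov$time[1]) / 24,
                        wt_imputed = FALSE, scr_imputed = FALSE)
      s$cov <- rbind(s$cov, add)
      s$cov <- s$cov[order(s$cov$time), , drop = FALSE]
      row.names(s$cov) <- NULL
    }
    etas <- c(s$truth$eta_bsv, s$truth$eta_bov[as.character(obs_occasions(s))])
    f <- subject_predictions(s, pop, etas)
    y <- f + stats::rnorm(length(f)) * residual_sd(f, pop$sigma_prop, pop$sigma_add)
    cens <- y < lloq
    s$obs$value <- ifelse(cens, lloq, y)
    s$obs$blq <- cens
    s
  }))
  cohort(unname(subjects),
         log = c(x$log, list(list(rule = "simulate_observations", seed = seed))))
}
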