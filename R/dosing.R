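# AUC24/MIC-targeted dose optimization: probability of target attainment
# (PTA) under a log-normal clearance distribution (population prior for
# empirical dosing, MAP posterior for Bayesian dosing), exhaustive
# dose x interval grid search, and the legacy trough-based and
# weight-based comparators.

#' Therapeutic target policy
#'
#' @param auc_mic_low,auc_mic_high Target window for AUC24/MIC, hours
#'   (default 400-600).
#' @param mic Assumed MIC, mg/L (default 1).
#' @return A `target_policy` object.
#' @export
target_policy <- function(auc_mic_low = 400, auc_mic_high = 600, mic = 1) {
  if (!(auc_mic_low < auc_mic_high)) stop("auc_mic_low must be < auc_mic_high")
  if (mic <= 0) stop("mic must be positive")
  structure(list(auc_mic_low = auc_mic_low, auc_mic_high = auc_mic_high,
                 mic = mic), class = "target_policy")
}

#' Dose-search policy
#'
#' Defaults reflect the observed dosing range (5-31 mg/kg per dose) and
#' usual neonatal intervals: 5-30 mg/kg in 0.5 mg/kg steps, intervals
#' {6, 8, 12, 18, 24, 36, 48} h, 1-h infusions.
#'
#' @param dose_per_kg_min,dose_per_kg_max,dose_per_kg_step mg/kg grid.
#' @param intervals Allowed dosing intervals, hours.
#' @param infusion_duration Hours.
#' @param dose_round_mg Absolute-dose rounding step, mg.
#' @param max_adjustment Cap on the trough-based dose scaling factor when
#'   the observed trough is at or below the LLOQ.
#' @return A `dosing_policy` object.
#' @export
dosing_policy <- function(dose_per_kg_min = 5, dose_per_kg_max = 30,
                          dose_per_kg_step = 0.5,
                          intervals = c(6, 8, 12, 18, 24, 36, 48),
                          infusion_duration = 1, dose_round_mg = 0.1,
                          max_adjustment = 4) {
  if (dose_per_kg_min <= 0 || dose_per_kg_max < dose_per_kg_min ||
      dose_per_kg_step <= 0 || !length(intervals) || any(intervals <= 0)) {
    stop("invalid dosing policy grid")
  }
  structure(list(dose_per_kg_min = dose_per_kg_min,
                 dose_per_kg_max = dose_per_kg_max,
                 dose_per_kg_step = dose_per_kg_step,
                 intervals = sort(intervals),
                 infusion_duration = infusion_duration,
                 dose_round_mg = dose_round_mg,
                 max_adjustment = max_adjustment),
            class = "dosing_policy")
}

#' Log-normal clearance deviation distributions
#'
#' The only random effects of the model act on clearance, so any individual
#' AUC distribution is log-normal and fully described by the mean and
#' variance of the log-scale clearance deviation `eta` from the
#' covariate-typical value. `cl_prior()` is the population prior
#' (BSV + BOV variance, mean zero) used by empirical dosing; and
#' `cl_posterior()` carries a MAP posterior's between-subject effect
#' forward to a new dosing occasion, where the between-occasion effect
#' regenerates from its prior.
#'
#' @param pop A [pop_params()] object.
#' @param estimate An `individual_estimate` from [map_estimate()].
#' @return A `cl_dist` object with fields `mu` and `var`.
#' @export
cl_prior <- function(pop) {
  structure(list(mu = 0, var = pop$omega2_bsv + pop$omega2_bov,
                 kind = "prior"), class = "cl_dist")
}

#' @rdname cl_prior
#' @param horizon `"current_occasion"` (default): the forecast applies to
#'   the ongoing treatment course, so the occasion effect estimated from
#'   the measurements persists (maintenance-dose adjustment, the usual TDM
#'   setting). `"new_occasion"`: the forecast applies to a later, separate
#'   course; the between-occasion effect regenerates from its prior and
#'   only the between-subject effect carries over.
#' @export
cl_posterior <- function(estimate, pop,
                         horizon = c("current_occasion", "new_occasion")) {
  stopifnot(inherits(estimate, "individual_estimate"))
  horizon <- match.arg(horizon)
  cov <- estimate$posterior_covariance
  if (horizon == "new_occasion" || length(estimate$eta_bov) == 0) {
    mu <- estimate$eta_bsv
    var <- cov["bsv", "bsv"] + pop$omega2_bov
  } else {
    occ <- names(estimate$eta_bov)[length(estimate$eta_bov)]
    nm <- paste0("bov_occ", occ)
    mu <- estimate$eta_bsv + estimate$eta_bov[[occ]]
    v <- as.numeric(colnames(cov) %in% c("bsv", nm))
    var <- as.numeric(t(v) %*% cov %*% v)
  }
  structure(list(mu = mu, var = var, kind = "posterior", horizon = horizon),
            class = "cl_dist")
}

#' @rdname cl_prior
#' @param mu,var Mean and variance of the log clearance deviation (a
#'   zero-variance distribution is a point mass).
#' @export
cl_dist <- function(mu, var) {
  if (var < 0) stop("var must be non-negative")
  structure(list(mu = mu, var = var, kind = "custom"), class = "cl_dist")
}

#' Probability of attaining the AUC24/MIC target
#'
#' Probability that the steady-state AUC24/MIC falls inside the target
#' window under an individual clearance distribution. Since the random
#' effects act on clearance only, the AUC is log-normal and the default is
#' the closed form
#' `Phi((log(high*MIC) - m)/s) - Phi((log(low*MIC) - m)/s)` with
#' `m = log(D24 / CL_typical) - mu`; a Monte-Carlo path (`method = "mc"`)
#' is kept for generality and cross-checking. Residual assay error is
#' deliberately excluded: the target is exposure, not measurement.
#'
#' @param reg A [regimen()].
#' @param covariates List with `wt` (kg), `pma` (days), `scr` (umol/L).
#' @param dist A [cl_dist()] (prior, posterior, or custom).
#' @param pop A [pop_params()] object.
#' @param policy A [target_policy()].
#' @param method `"closed_form"` (default) or `"mc"`.
#' @param n_samples Monte-Carlo sample size (default 4000; < 100 warns).
#' @param seed Seed for the Monte-Carlo draws.
#' @param eta_samples Optional pre-drawn standard-normal vector recycled
#'   across calls (common random numbers for grid searches).
#' @return The attainment probability in [0, 1].
#' @export
pta <- function(reg, covariates, dist, pop, policy = target_policy(),
                method = c("closed_form", "mc"), n_samples = 4000,
                seed = NULL, eta_samples = NULL) {
  stopifnot(inherits(reg, "regimen"), inherits(dist, "cl_dist"),
            inherits(policy, "target_policy"), inherits(pop, "pop_params"))
  method <- match.arg(method)
  typ <- typical_params(covariates$wt, covariates$pma, covariates$scr, pop)
  d24 <- (24 / reg$interval) * reg$dose
  lo <- policy$auc_mic_low * policy$mic
  hi <- policy$auc_mic_high * policy$mic
  m <- log(d24 / typ$cl) - dist$mu
  s <- sqrt(dist$var)
  if (method == "closed_form") {
    if (s == 0) return(as.numeric(exp(m) >= lo && exp(m) <= hi))
    return(stats::pnorm((log(hi) - m) / s) - stats::pnorm((log(lo) - m) / s))
  }
  if (n_samples < 100) warning("n_samples < 100 gives unstable PTA estimates")
  z <- if (!is.null(eta_samples)) eta_samples
       else with_seed(seed, stats::rnorm(n_samples))
  lauc <- m - s * z
  mean(lauc >= log(lo) & lauc <= log(hi))
}

.snap_dose <- function(dose_mg, wt, dosing) {
  per_kg <- dose_mg / wt
  per_kg <- round(per_kg / dosing$dose_per_kg_step) * dosing$dose_per_kg_step
  per_kg <- min(max(per_kg, dosing$dose_per_kg_min), dosing$dose_per_kg_max)
  round(per_kg * wt / dosing$dose_round_mg) * dosing$dose_round_mg
}

#' Optimize a regimen over the dose x interval grid
#'
#' Exhaustive evaluation of every dose (mg/kg grid scaled by weight) and
#' interval in the policy, maximizing PTA. Monte-Carlo evaluations share
#' common random numbers across grid points to stabilize the argmax. Ties
#' within 1e-3 of the maximum break toward the lowest total daily dose,
#' then the longest interval (minimizing exposure and handling).
#'
#' @inheritParams pta
#' @param dosing A [dosing_policy()].
#' @return A `pta_result`: `optimum` ([regimen()]), `pta` (at the optimum),
#'   `grid` (data.frame of all regimens with their PTA),
#'   `auc24_quantiles` (5/25/50/75/95% of the AUC24 distribution at the
#'   optimum), `ss_trough`/`ss_peak` (at the median individual clearance),
#'   `tie_break_applied`.
#' @export
optimize_regimen <- function(dist, covariates, pop, policy = target_policy(),
                             dosing = dosing_policy(),
                             method = c("closed_form", "mc"),
                             n_samples = 4000, seed = NULL) {
  method <- match.arg(method)
  per_kg <- seq(dosing$dose_per_kg_min, dosing$dose_per_kg_max,
                by = dosing$dose_per_kg_step)
  doses_mg <- unique(round(per_kg * covariates$wt / dosing$dose_round_mg) *
                     dosing$dose_round_mg)
  doses_mg <- doses_mg[doses_mg > 0]
  grid <- expand.grid(dose = doses_mg, interval = dosing$intervals,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[grid$interval >= dosing$infusion_duration, , drop = FALSE]
  if (!nrow(grid)) stop("empty feasible dosing grid")
  z <- if (method == "mc") with_seed(seed, stats::rnorm(n_samples)) else NULL
  grid$pta <- vapply(seq_len(nrow(grid)), function(i) {
    pta(regimen(grid$dose[i], grid$interval[i], dosing$infusion_duration),
        covariates, dist, pop, policy, method = method,
        n_samples = n_samples, eta_samples = z)
  }, 0)
  best <- max(grid$pta)
  cand <- grid[grid$pta >= best - 1e-3, , drop = FALSE]
  cand$daily <- 24 / cand$interval * cand$dose
  cand <- cand[order(cand$daily, -cand$interval), , drop = FALSE]
  tie <- nrow(cand) > 1
  opt <- regimen(cand$dose[1], cand$interval[1], dosing$infusion_duration)
  typ <- typical_params(covariates$wt, covariates$pma, covariates$scr, pop)
  m <- log((24 / opt$interval) * opt$dose / typ$cl) - dist$mu
  qs <- stats::qlnorm(c(0.05, 0.25, 0.5, 0.75, 0.95), meanlog = m,
                      sdlog = sqrt(dist$var))
  med <- individual_params(typ, dist$mu)
  ss <- steady_state_profile(opt, med)
  structure(list(optimum = opt, pta = cand$pta[1], grid = grid,
                 auc24_quantiles = stats::setNames(qs, c("q05", "q25", "q50", "q75", "q95")),
                 ss_trough = ss$trough, ss_peak = ss$peak,
                 tie_break_applied = tie, dist_kind = dist$kind),
            class = "pta_result")
}

#' @export
print.pta_result <- function(x, ...) {
  cat(sprintf("optimal regimen (%s distribution): %.4g mg q%gh, PTA %.3f%s\n",
              x$dist_kind, x$optimum$dose, x$optimum$interval, x$pta,
              if (x$tie_break_applied) " (tie broken to lowest daily dose)" else ""))
  cat(sprintf("  AUC24 median %.0f (90%% interval %.0f-%.0f) mg.h/L; ss trough %.2f, peak %.2f mg/L\n",
              x$auc24_quantiles[["q50"]], x$auc24_quantiles[["q05"]],
              x$auc24_quantiles[["q95"]], x$ss_trough, x$ss_peak))
  invisible(x)
}

#' Model-based empirical dosing (before any measurement)
#'
#' Optimizes the regimen under the population prior: appropriate before
#' the first dose, when only covariates are known.
#'
#' @inheritParams optimize_regimen
#' @export
empirical_regimen <- function(covariates, pop, policy = target_policy(),
                              dosing = dosing_policy(),
                              method = c("closed_form", "mc"),
                              n_samples = 4000, seed = NULL) {
  optimize_regimen(cl_prior(pop), covariates, pop, policy, dosing,
                   method = method, n_samples = n_samples, seed = seed)
}

#' Model-based Bayesian dose optimization
#'
#' MAP-estimates the subject's random effects from the available
#' concentrations (one trough, preferably plus one peak, suffices), then
#' optimizes the regimen under the posterior clearance distribution,
#' evaluated at the covariates of the subject's most recent dose.
#'
#' @param subject A preprocessed [subject_record()] with >= 1 observation.
#' @inheritParams optimize_regimen
#' @inheritParams cl_posterior
#' @return A `pta_result`; the MAP estimate is attached as
#'   `$individual_estimate`.
#' @export
bayesian_regimen <- function(subject, pop, policy = target_policy(),
                             dosing = dosing_policy(),
                             horizon = c("current_occasion", "new_occasion"),
                             method = c("closed_form", "mc"),
                             n_samples = 4000, seed = NULL) {
  stopifnot(inherits(subject, "subject_record"))
  if (!nrow(subject$obs)) stop("Bayesian dosing requires at least one observation")
  est <- map_estimate(subject, pop)
  covs <- covariates_at(subject, max(subject$doses$time))
  out <- optimize_regimen(cl_posterior(est, pop, match.arg(horizon)), covs,
                          pop, policy, dosing,
                          method = method, n_samples = n_samples, seed = seed)
  out$individual_estimate <- est
  out
}

#' Trough-based dose adjustment (legacy comparator)
#'
#' Scales the current dose by `target_trough / observed_ss_trough`
#' (linear PK), snaps it to the mg/kg grid, and keeps the interval. An
#' observed trough at or below the LLOQ is flagged and the scaling factor
#' capped at the policy maximum.
#'
#' @param current The current [regimen()].
#' @param observed_ss_trough Measured steady-state trough, mg/L (> 0).
#' @param wt Current body weight, kg (for grid snapping).
#' @param target_trough Target trough, mg/L (default 8.5, the midpoint of
#'   the previously recommended 7-10 mg/L window).
#' @param dosing A [dosing_policy()].
#' @param lloq Assay LLOQ, mg/L.
#' @return Adjusted `regimen`; attribute `"lloq_capped"` is `TRUE` when
#'   the cap was applied.
#' @export
trough_adjust <- function(current, observed_ss_trough, wt,
                          target_trough = 8.5, dosing = dosing_policy(),
                          lloq = 1) {
  stopifnot(inherits(current, "regimen"))
  if (observed_ss_trough <= 0) stop("observed trough must be positive")
  capped <- FALSE
  scale <- target_trough / observed_ss_trough
  if (observed_ss_trough <= lloq && scale > dosing$max_adjustment) {
    scale <- dosing$max_adjustment
    capped <- TRUE
  }
  new_dose <- .snap_dose(current$dose * scale, wt, dosing)
  out <- regimen(new_dose, current$interval, current$infusion_duration,
                 current$n_doses)
  attr(out, "lloq_capped") <- capped
  out
}

#' Weight-based initial dose
#'
#' @param wt Body weight, kg (> 0).
#' @param mg_per_kg Per-kg dose policy (default 14 mg/kg, the cohort
#'   median).
#' @param interval Dosing interval, hours.
#' @param dosing A [dosing_policy()] (grid snapping and infusion duration).
#' @return A `regimen`.
#' @export
weight_based_initial <- function(wt, mg_per_kg = 14, interval = 8,
                                 dosing = dosing_policy()) {
  if (!is.finite(wt) || wt <= 0) stop("wt must be positive")
  regimen(.snap_dose(mg_per_kg * wt, wt, dosing), interval,
          dosing$infusion_duration)
}

# reconstruct a subject's current maintenance regimen from the dose events
# of their last occasion
current_regimen <- function(subject, dosing = dosing_policy()) {
  d <- subject$doses
  d <- d[d$occasion == max(d$occasion), , drop = FALSE]
  interval <- if (nrow(d) > 1) stats::median(diff(d$time)) else 12
  regimen(d$amount[nrow(d)], interval, d$duration[nrow(d)])
}

#' Compare dosing approaches on a simulated cohort
#'
#' For every subject of a synthetic cohort (carrying simulation truth),
#' computes the per-subject PTA attained by four approaches: (1) keeping
#' the initial regimen, (2) trough-based adjustment to a steady-state
#' trough target, (3) model-based empirical optimization (covariates
#' only), and (4) model-based Bayesian optimization (MAP from the
#' subject's observations).
#'
#' The reference AUC distribution for "attained PTA" is, by default, each
#' subject's MAP posterior (between-subject effect) combined with a fresh
#' between-occasion effect — the only evaluation available with real data,
#' where no truth exists. `eval_dist = "truth"` instead centers the
#' distribution on the subject's simulated true between-subject effect.
#' The trough measurement feeding approach (2) is simulated from the
#' subject's true parameters at steady state of the initial regimen, with
#' residual assay error.
#'
#' @param x A `vanc_cohort` whose subjects carry `truth` and observations.
#' @param pop A [pop_params()] object.
#' @param policy A [target_policy()].
#' @param dosing A [dosing_policy()].
#' @param seed Integer seed (trough measurement noise).
#' @param target_trough Trough target for approach (2), mg/L.
#' @param eval_dist `"posterior"` (default) or `"truth"`.
#' @return An `approach_comparison`: `per_subject` data.frame with the PTA
#'   of each approach, the percent change of the 24-h dose for the trough
#'   and Bayesian approaches, and the initial median AUC24; plus a
#'   `summary` list (median/min per approach).
#' @export
evaluate_approaches <- function(x, pop, policy = target_policy(),
                                dosing = dosing_policy(), seed = 1L,
                                target_trough = 8.5,
                                eval_dist = c("posterior", "truth")) {
  stopifnot(inherits(x, "vanc_cohort"))
  eval_dist <- match.arg(eval_dist)
  rows <- with_seed(seed, lapply(x$subjects, function(s) {
    if (is.null(s$truth)) stop("subject ", s$subject_id, " carries no simulation truth")
    est <- map_estimate(s, pop)
    covs <- covariates_at(s, max(s$doses$time))
    ref <- if (eval_dist == "posterior") cl_posterior(est, pop)
           else cl_dist(s$truth$eta_bsv, pop$omega2_bov)
    reg0 <- current_regimen(s, dosing)
    # simulated steady-state trough of the initial regimen, with assay error
    last_occ <- as.character(max(s$doses$occasion))
    eta_occ <- if (last_occ %in% names(s$truth$eta_bov)) s$truth$eta_bov[[last_occ]] else 0
    typ <- typical_params(covs$wt, covs$pma, covs$scr, pop)
    p_true <- individual_params(typ, s$truth$eta_bsv, eta_occ)
    tr_true <- steady_state_profile(reg0, p_true)$trough
    tr_obs <- max(tr_true + stats::rnorm(1) *
                    residual_sd(tr_true, pop$sigma_prop, pop$sigma_add), 0.1)
    reg_tr <- trough_adjust(reg0, tr_obs, covs$wt, target_trough, dosing)
    opt_emp <- optimize_regimen(cl_prior(pop), covs, pop, policy, dosing)
    opt_bay <- optimize_regimen(cl_posterior(est, pop), covs, pop, policy, dosing)
    pta_of <- function(reg) pta(reg, covs, ref, pop, policy)
    daily <- function(reg) 24 / reg$interval * reg$dose
    data.frame(
      subject_id = s$subject_id,
      pta_initial = pta_of(reg0),
      pta_trough = pta_of(reg_tr),
      pta_empirical = pta_of(opt_emp$optimum),
      pta_bayesian = pta_of(opt_bay$optimum),
      observed_trough = tr_obs,
      auc24_initial_median = daily(reg0) / (typ$cl * exp(ref$mu)),
      dose_change_trough_pct = 100 * (daily(reg_tr) / daily(reg0) - 1),
      dose_change_bayes_pct = 100 * (daily(opt_bay$optimum) / daily(reg0) - 1),
      row.names = NULL)
  }))
  per_subject <- do.call(rbind, c(unname(rows), list(make.row.names = FALSE)))
  summarize <- function(col) {
    v <- per_subject[[col]]
    c(median = stats::median(v), min = min(v), mean = mean(v))
  }
  structure(list(per_subject = per_subject,
                 summary = list(initial = summarize("pta_initial"),
                                trough = summarize("pta_trough"),
                                empirical = summarize("pta_empirical"),
                                bayesian = summarize("pta_bayesian")),
                 eval_dist = eval_dist),
            class = "approach_comparison")
}

#' @export
print.approach_comparison <- function(x, ...) {
  cat(sprintf("dosing-approach comparison (%d subjects, %s evaluation)\n",
              nrow(x$per_subject), x$eval_dist))
  for (nm in names(x$summary)) {
    s <- x$summary[[nm]]
    cat(sprintf("  %-10s median PTA %.3f, min %.3f, mean %.3f\n",
                nm, s[["median"]], s[["min"]], s[["mean"]]))
  }
  invisible(x)
}
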