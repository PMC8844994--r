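# Population NLME fitting by the Laplace approximation with interaction:
# per subject, the marginal -2 log likelihood is approximated at the
# conditional mode of the random effects, with the M3 censored terms kept
# inside the same approximation. Fixed effects are estimated on the log
# scale; allometric exponents are fixed by default.

.estimable <- c("tvcl", "tvvc", "tvq", "tvvp", "hill", "mat50",
                "scr_exponent", "omega_bsv", "omega_bov",
                "sigma_prop", "sigma_add")

# log-scale theta -> pop_params update
.theta_to_pop <- function(theta, base) {
  args <- list(tvcl = base$tvcl, tvvc = base$tvvc, tvq = base$tvq,
               tvvp = base$tvvp, hill = base$hill, mat50 = base$mat50,
               scr_exponent = base$scr_exponent,
               wt_exp_cl_q = base$wt_exp_cl_q, wt_exp_v = base$wt_exp_v,
               cv_bsv = base$cv_bsv, cv_bov = base$cv_bov,
               sigma_prop = base$sigma_prop, sigma_add = base$sigma_add,
               wt_ref = base$wt_ref, scr_ref = base$scr_ref)
  for (nm in names(theta)) {
    v <- exp(theta[[nm]])
    if (nm == "omega_bsv") args$cv_bsv <- omega2_to_cv(v^2)
    else if (nm == "omega_bov") args$cv_bov <- omega2_to_cv(v^2)
    else args[[nm]] <- v
  }
  do.call(pop_params, args)
}

.pop_to_theta <- function(pop, names) {
  vals <- vapply(names, function(nm) {
    switch(nm,
           omega_bsv = sqrt(pop$omega2_bsv),
           omega_bov = sqrt(pop$omega2_bov),
           pop[[nm]])
  }, 0)
  log(stats::setNames(vals, names))
}

# Laplace -2 log marginal likelihood contribution of one subject:
# neg2log_posterior at the conditional mode + log det(Omega) + log det(H/2)
# (the prior's and the Laplace integral's 2*pi terms cancel; the data
# normal constant is dropped).
.subject_ofv <- function(subject, pop, warm = NULL) {
  occs <- obs_occasions(subject)
  est <- map_estimate(subject, pop, restarts = 2, start = warm)
  mode <- c(est$eta_bsv, est$eta_bov)
  # posterior_covariance = 2 * H^-1, so log det(H/2) = -log det(cov)
  ld_cov <- determinant(est$posterior_covariance, logarithm = TRUE)
  if (ld_cov$sign <= 0) return(list(ofv = NA_real_, mode = mode, est = est))
  ld_omega <- log(pop$omega2_bsv) + length(occs) * log(pop$omega2_bov)
  list(ofv = est$objective + ld_omega - as.numeric(ld_cov$modulus),
       mode = mode, est = est)
}

#' Fit the population model by Laplace approximation
#'
#' Maximizes the Laplace-approximated marginal likelihood (conditional
#' modes plus log-determinant correction per subject; residual error
#' evaluated at individual predictions, i.e. with interaction; BLQ terms by
#' the M3 method inside the same approximation). Fixed effects and variance
#' components are estimated on the log scale.
#'
#' @param x A preprocessed `vanc_cohort`.
#' @param init A [pop_params()] object of initial values; parameters not
#'   estimated stay fixed at these values.
#' @param fixed Character vector of parameter names to fix. Allometric
#'   exponents are always fixed (0.75 / 1). Estimable names:
#'   `tvcl`, `tvvc`, `tvq`, `tvvp`, `hill`, `mat50`, `scr_exponent`,
#'   `omega_bsv`, `omega_bov`, `sigma_prop`, `sigma_add`.
#' @param estimate Character vector of parameter names to estimate
#'   (overrides `fixed`); default: everything except the allometric
#'   exponents.
#' @param compute_se Compute standard errors, condition number and
#'   shrinkage from the outer Hessian (default `TRUE`; the costly part).
#' @param control List: `reltol` outer tolerance (default 1e-6), `maxit`.
#' @return A `fit_result` with `estimates` (a `pop_params`), `theta`
#'   (log-scale estimates), `ofv`, `se` and `ci90` (log-scale SEs;
#'   `estimate * exp(+/- 1.645 se)` CIs), `condition_number` (eigenvalue
#'   ratio of the correlation matrix of estimates; reference limit 1000),
#'   `shrinkage` (percent, per random effect and pooled), `ebe_table`,
#'   `converged`, `gradient_norm`.
#' @export
nlme_fit <- function(x, init = pop_params(), fixed = character(),
                     estimate = NULL, compute_se = TRUE,
                     control = list()) {
  stopifnot(inherits(x, "vanc_cohort"), inherits(init, "pop_params"))
  est_names <- if (!is.null(estimate)) estimate else setdiff(.estimable, fixed)
  bad <- setdiff(est_names, .estimable)
  if (length(bad)) stop("not estimable: ", paste(bad, collapse = ", "))
  subjects <- Filter(function(s) nrow(s$obs) > 0, x$subjects)
  if (!length(subjects)) stop("no subjects with observations")
  reltol <- control$reltol %||% 1e-6
  maxit <- control$maxit %||% 200
  warm <- new.env(parent = emptyenv())
  objective <- function(theta_vec) {
    theta <- stats::setNames(theta_vec, est_names)
    pop <- tryCatch(.theta_to_pop(as.list(theta), init), error = function(e) NULL)
    if (is.null(pop)) return(1e10)
    tot <- 0
    for (id in names(subjects)) {
      w <- if (exists(id, warm)) get(id, warm) else NULL
      r <- tryCatch(.subject_ofv(subjects[[id]], pop, warm = w),
                    error = function(e) NULL)
      if (is.null(r) || !is.finite(r$ofv)) return(1e10)
      assign(id, r$mode, warm)
      tot <- tot + r$ofv
    }
    tot
  }
  theta0 <- .pop_to_theta(init, est_names)
  opt <- stats::optim(theta0, objective, method = "BFGS",
                      control = list(reltol = reltol, maxit = maxit))
  theta_hat <- stats::setNames(opt$par, est_names)
  pop_hat <- .theta_to_pop(as.list(theta_hat), init)
  # gradient norm at the optimum (central differences, log scale)
  eps <- 1e-4
  grad <- vapply(seq_along(theta_hat), function(j) {
    tp <- theta_hat; tm <- theta_hat
    tp[j] <- tp[j] + eps; tm[j] <- tm[j] - eps
    (objective(tp) - objective(tm)) / (2 * eps)
  }, 0)
  se <- rep(NA_real_, length(est_names))
  cond <- NA_real_
  cov_theta <- NULL
  if (compute_se) {
    hess <- stats::optimHess(opt$par, objective)
    cov_theta <- tryCatch(2 * solve(hess), error = function(e) NULL)
    if (!is.null(cov_theta) && all(diag(cov_theta) > 0)) {
      se <- sqrt(diag(cov_theta))
      corr <- stats::cov2cor(cov_theta)
      ev <- eigen(corr, symmetric = TRUE, only.values = TRUE)$values
      cond <- max(ev) / max(min(ev), .Machine$double.eps)
    }
  }
  # empirical Bayes estimates and shrinkage at the final estimates
  ebes <- lapply(subjects, function(s) {
    e <- map_estimate(s, pop_hat, restarts = 2,
                      start = if (exists(s$subject_id, warm)) get(s$subject_id, warm) else NULL)
    list(bsv = e$eta_bsv, bov = e$eta_bov)
  })
  bsv <- vapply(ebes, function(e) e$bsv, 0)
  bov <- unlist(lapply(ebes, function(e) e$bov))
  sd0 <- function(v) if (length(v) > 1) stats::sd(v) else 0
  shr <- list(
    bsv_pct = 100 * (1 - sd0(bsv) / sqrt(pop_hat$omega2_bsv)),
    bov_pct = if (length(bov)) 100 * (1 - sd0(bov) / sqrt(pop_hat$omega2_bov)) else NA_real_,
    pooled_pct = 100 * (1 - sd0(c(bsv / sqrt(pop_hat$omega2_bsv),
                                  bov / sqrt(pop_hat$omega2_bov))))
  )
  ebe_table <- data.frame(subject_id = names(subjects), eta_bsv = bsv,
                          row.names = NULL)
  names_ci <- stats::setNames(exp(theta_hat), est_names)
  ci90 <- data.frame(parameter = est_names, estimate = names_ci,
                     lower = names_ci * exp(-1.645 * se),
                     upper = names_ci * exp(1.645 * se), row.names = NULL)
  structure(list(estimates = pop_hat, theta = theta_hat, ofv = opt$value,
                 se = stats::setNames(se, est_names), ci90 = ci90,
                 cov_theta = cov_theta, condition_number = cond,
                 condition_reference_limit = 1000,
                 shrinkage = shr, ebe_table = ebe_table,
                 converged = opt$convergence == 0,
                 gradient_norm = sqrt(sum(grad^2)),
                 n_subjects = length(subjects)),
            class = "fit_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Laplace population fit: OFV %.3f, %d subjects%s\n", x$ofv,
              x$n_subjects, if (x$converged) "" else " [NOT CONVERGED]"))
  print(x$ci90, digits = 4)
  if (is.finite(x$condition_number)) {
    cat(sprintf("condition number %.1f (reference limit %d)\n",
                x$condition_number, x$condition_reference_limit))
  }
  cat(sprintf("shrinkage: BSV %.1f%%, BOV %.1f%%, pooled %.1f%%\n",
              x$shrinkage$bsv_pct, x$shrinkage$bov_pct, x$shrinkage$pooled_pct))
  invisible(x)
}

#' Likelihood-ratio test p-value for a change in OFV
#'
#' Upper-tail chi-square probability of `|dofv|` at `df` degrees of
#' freedom; the change in the -2 log likelihood objective between nested
#' models is asymptotically chi-square.
#'
#' @param dofv Change in OFV (its absolute value is used).
#' @param df Degrees of freedom (>= 1).
#' @return The p-value.
#' @examples
#' lrt_pvalue(5.583, 2) # ~0.06
#' @export
lrt_pvalue <- function(dofv, df) {
  if (df < 1) stop("df must be >= 1")
  stats::pchisq(abs(dofv), df = df, lower.tail = FALSE)
}

#' Nonparametric bootstrap of the population fit
#'
#' Resamples subjects with replacement, refits each replicate and reports
#' per-parameter means and percentile 90% confidence intervals.
#' Non-convergent replicates are dropped and counted.
#'
#' @param x A preprocessed `vanc_cohort`.
#' @param n Number of resampled data sets (1000 is customary for reported
#'   intervals; scale down for exploratory runs).
#' @param seed Integer seed for the resampling indices.
#' @param init,fixed,estimate,control Passed to [nlme_fit()].
#' @return A `bootstrap_result`: `n_resamples`, `n_failed`, `means`,
#'   `ci90` (5th/95th percentiles), `estimates` (replicate matrix).
#' @export
bootstrap_fit <- function(x, n = 1000, seed = 1L, init = pop_params(),
                          fixed = character(), estimate = NULL,
                          control = list()) {
  stopifnot(inherits(x, "vanc_cohort"))
  ids <- names(x$subjects)
  idx <- with_seed(seed, matrix(sample.int(length(ids), n * length(ids),
                                           replace = TRUE), nrow = n))
  reps <- vector("list", n)
  failed <- 0L
  for (b in seq_len(n)) {
    subs <- x$subjects[idx[b, ]]
    # resampled subjects get fresh unique ids
    subs <- lapply(seq_along(subs), function(j) {
      s <- subs[[j]]; s$subject_id <- paste0("bs", b, "_", j); s
    })
    cb <- cohort(subs)
    fit <- tryCatch(nlme_fit(cb, init = init, fixed = fixed,
                             estimate = estimate, compute_se = FALSE,
                             control = control),
                    error = function(e) NULL)
    if (is.null(fit) || !fit$converged) { failed <- failed + 1L; next }
    reps[[b]] <- exp(fit$theta)
  }
  reps <- do.call(rbind, reps[!vapply(reps, is.null, TRUE)])
  if (is.null(reps) || !nrow(reps)) stop("all bootstrap replicates failed")
  structure(list(n_resamples = n, n_failed = failed,
                 resample_indices = idx,
                 means = colMeans(reps),
                 ci90 = apply(reps, 2, stats::quantile, probs = c(0.05, 0.95)),
                 estimates = reps),
            class = "bootstrap_result")
}

#' Conditional weighted residuals
#'
#' FOCE-type linearization at each subject's conditional mode: with
#' `G = df/deta` at the mode, the marginal mean is `f(eta_hat) - G eta_hat`
#' and the covariance `G Omega G' + diag(sd^2)` with the residual SD at the
#' individual prediction. Residuals are decorrelated with the inverse
#' Cholesky root. BLQ observations are excluded.
#'
#' @param x A preprocessed `vanc_cohort`.
#' @param pop A `pop_params` object (e.g. `fit$estimates`).
#' @return data.frame: `subject_id`, `time`, `dv`, `pred` (population),
#'   `ipred` (individual), `cwres`.
#' @export
cwres <- function(x, pop) {
  stopifnot(inherits(x, "vanc_cohort"), inherits(pop, "pop_params"))
  out <- lapply(x$subjects, function(s) {
    keep <- !s$obs$blq
    if (!any(keep)) return(NULL)
    est <- map_estimate(s, pop, restarts = 2)
    mode <- c(est$eta_bsv, est$eta_bov)
    k <- length(mode)
    f <- subject_predictions(s, pop, mode)
    pred0 <- subject_predictions(s, pop, rep(0, k))
    eps <- 1e-4
    G <- vapply(seq_len(k), function(j) {
      ep <- mode; em <- mode
      ep[j] <- ep[j] + eps; em[j] <- em[j] - eps
      (subject_predictions(s, pop, ep) - subject_predictions(s, pop, em)) / (2 * eps)
    }, numeric(nrow(s$obs)))
    G <- matrix(G, nrow = nrow(s$obs))[keep, , drop = FALSE]
    fk <- f[keep]
    y <- s$obs$value[keep]
    omega <- diag(c(pop$omega2_bsv, rep(pop$omega2_bov, k - 1)), k)
    sdk <- residual_sd(pmax(fk, 0), pop$sigma_prop, pop$sigma_add)
    V <- G %*% omega %*% t(G) + diag(sdk^2, length(fk))
    mu <- fk - as.numeric(G %*% mode)
    w <- backsolve(chol(V), y - mu, transpose = TRUE)
    data.frame(subject_id = s$subject_id, time = s$obs$time[keep], dv = y,
               pred = pred0[keep], ipred = fk, cwres = as.numeric(w),
               row.names = NULL)
  })
  do.call(rbind, c(out[!vapply(out, is.null, TRUE)], list(make.row.names = FALSE)))
}

#' Share of clearance variability explained by covariates
#'
#' Reconstruction of a variance-explained metric: the variance across
#' subjects of log typical clearance with only the named covariates active
#' (the others held at their reference values), divided by the total
#' variability `Var(log CL_typical, all active) + omega2_bsv + omega2_bov`,
#' as a percentage. Covariates are evaluated at each subject's first dose.
#'
#' @param x A preprocessed `vanc_cohort`.
#' @param pop A `pop_params` object.
#' @param covariates Subset of `c("wt", "pma", "scr")`; empty gives 0.
#' @return Percent of clearance variability explained.
#' @export
variance_explained <- function(x, pop, covariates = c("wt", "pma", "scr")) {
  stopifnot(inherits(x, "vanc_cohort"), inherits(pop, "pop_params"))
  if (!length(x$subjects)) stop("empty cohort")
  bad <- setdiff(covariates, c("wt", "pma", "scr"))
  if (length(bad)) stop("unknown covariates: ", paste(bad, collapse = ", "))
  terms <- vapply(x$subjects, function(s) {
    t0 <- if (nrow(s$doses)) min(s$doses$time) else min(s$cov$time)
    cv <- covariates_at(s, t0)
    c(wt = pop$wt_exp_cl_q * log(cv$wt / pop$wt_ref),
      pma = log(maturation(cv$pma, pop$hill, pop$mat50)),
      scr = pop$scr_exponent * log(pop$scr_ref / cv$scr))
  }, numeric(3))
  var_subset <- if (length(covariates)) {
    stats::var(colSums(terms[covariates, , drop = FALSE]))
  } else 0
  var_all <- stats::var(colSums(terms))
  100 * var_subset / (var_all + pop$omega2_bsv + pop$omega2_bov)
}
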