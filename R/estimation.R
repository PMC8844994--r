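# Individual-level estimation: the -2 log posterior of a subject's random
# effects (M3 censored terms for BLQ records, combined-error likelihood
# with interaction), its MAP mode, and Laplace posterior draws.

# occasions of a subject that carry observations (these get a BOV eta)
obs_occasions <- function(subject) sort(unique(subject$obs$occasion))

# covariate-typical parameters per occasion, evaluated at the occasion's
# first dose (falling back to the first observation for dose-less occasions)
occasion_typical <- function(subject, pop) {
  occs <- sort(unique(c(subject$doses$occasion, subject$obs$occasion)))
  out <- lapply(occs, function(oc) {
    t0 <- if (any(subject$doses$occasion == oc)) {
      min(subject$doses$time[subject$doses$occasion == oc])
    } else min(subject$obs$time[subject$obs$occasion == oc])
    cv <- covariates_at(subject, t0)
    if (any(is.na(unlist(cv)))) {
      stop("subject ", subject$subject_id,
           " has incomplete covariates; run impute_covariates() first")
    }
    typical_params(cv$wt, cv$pma, cv$scr, pop)
  })
  stats::setNames(out, as.character(occs))
}

# individual predictions at all observation times for a given eta vector
# (eta[1] = BSV, remainder = BOV per observed occasion, in obs_occasions()
# order). Covariates and CL are occasion-specific; the full dose history is
# superposed with the parameters of the observation's occasion.
subject_predictions <- function(subject, pop, etas,
                                typ = occasion_typical(subject, pop)) {
  occs <- obs_occasions(subject)
  pred <- numeric(nrow(subject$obs))
  for (k in seq_along(occs)) {
    oc <- occs[k]
    sel <- subject$obs$occasion == oc
    p <- individual_params(typ[[as.character(oc)]], etas[1],
                           if (length(etas) > 1) etas[1 + k] else 0)
    pred[sel] <- concentration(subject$obs$time[sel], subject$doses, p)
  }
  pred
}

#' -2 log posterior of a subject's random effects
#'
#' Sums, over non-BLQ observations, `((obs - pred)/sd)^2 + 2*log(sd)` with
#' `sd = residual_sd(pred)` evaluated at the individual prediction
#' (interaction); adds `-2 * log(Phi((lloq - pred)/sd))` for each BLQ
#' observation (M3 method); and adds the prior `eta' Omega^-1 eta` with a
#' block-diagonal Omega built from the BSV and BOV variances. Constant
#' `2*pi` terms are omitted throughout.
#'
#' @param etas Numeric vector: the BSV effect followed by one BOV effect
#'   per observed occasion (ordered as [obs_occasions()]).
#' @param subject A preprocessed [subject_record()].
#' @param pop A [pop_params()] object.
#' @param typ Precomputed occasion-typical parameters (internal use; the
#'   default recomputes them from the subject's covariates).
#' @return Scalar objective value.
#' @export
neg2log_posterior <- function(etas, subject, pop,
                              typ = occasion_typical(subject, pop)) {
  occs <- obs_occasions(subject)
  if (length(etas) != 1 + length(occs)) {
    stop("etas must have length 1 + number of observed occasions (",
         1 + length(occs), ")")
  }
  prior <- etas[1]^2 / pop$omega2_bsv
  if (length(occs)) prior <- prior + sum(etas[-1]^2) / pop$omega2_bov
  if (!nrow(subject$obs)) return(prior)
  pred <- subject_predictions(subject, pop, etas, typ)
  if (any(!is.finite(pred))) stop("non-finite individual prediction")
  sd <- residual_sd(pred, pop$sigma_prop, pop$sigma_add)
  blq <- subject$obs$blq
  ll <- 0
  if (any(!blq)) {
    r <- (subject$obs$value[!blq] - pred[!blq]) / sd[!blq]
    ll <- ll + sum(r^2 + 2 * log(sd[!blq]))
  }
  if (any(blq)) {
    ll <- ll - 2 * sum(stats::pnorm(subject$obs$lloq[blq], mean = pred[blq],
                                    sd = sd[blq], log.p = TRUE))
  }
  ll + prior
}

#' MAP Bayesian estimate of a subject's random effects
#'
#' Minimizes [neg2log_posterior()] by quasi-Newton (BFGS) from zero with
#' deterministic jittered restarts; the posterior covariance is twice the
#' inverse Hessian of the objective at the mode (the objective is -2 log
#' posterior). A subject without observations returns the prior (mode zero,
#' covariance Omega). Non-convergence after all restarts is flagged, not
#' silently ignored.
#'
#' @param subject A preprocessed [subject_record()].
#' @param pop A [pop_params()] object.
#' @param restarts Number of additional jittered starts (default 3).
#' @param start Optional warm-start eta vector.
#' @return An `individual_estimate`: `eta_bsv`, `eta_bov` (named by
#'   occasion), `objective` (-2 log posterior at the mode),
#'   `posterior_covariance`, `params_by_occasion` (derived `pk_params` at
#'   the mode), `converged`, `restarts_used`.
#' @export
map_estimate <- function(subject, pop, restarts = 3, start = NULL) {
  stopifnot(inherits(subject, "subject_record"), inherits(pop, "pop_params"))
  occs <- obs_occasions(subject)
  k <- 1 + length(occs)
  typ <- occasion_typical(subject, pop)
  nm <- c("bsv", if (length(occs)) paste0("bov_occ", occs))
  if (!nrow(subject$obs)) {
    omega <- diag(c(pop$omega2_bsv, rep(pop$omega2_bov, length(occs))), k)
    dimnames(omega) <- list(nm, nm)
    est <- list(eta_bsv = 0,
                eta_bov = stats::setNames(rep(0, length(occs)), as.character(occs)),
                objective = 0, posterior_covariance = omega,
                params_by_occasion = lapply(typ, individual_params),
                converged = TRUE, restarts_used = 0L)
    return(structure(est, class = "individual_estimate"))
  }
  # bounded objective for the optimizer: |eta| > 10 (a >20000-fold CL
  # shift) is treated as out of bounds with a smooth pull-back, and any
  # numerical failure as a large finite value, so line searches cannot
  # escape the plausible region
  fn <- function(e) {
    if (any(abs(e) > 10)) return(1e8 * (1 + sum(pmax(abs(e) - 10, 0)^2)))
    tryCatch(neg2log_posterior(e, subject, pop, typ), error = function(err) 1e9)
  }
  # Exact 1-D reduction for the single-occasion case: predictions depend
  # on the etas only through u = eta_bsv + eta_bov, and the prior
  # minimized over a fixed sum is u^2 / (omega2_bsv + omega2_bov). The
  # posterior Hessian follows analytically from the 1-D data curvature.
  if (length(occs) == 1) {
    w_b <- pop$omega2_bsv; w_o <- pop$omega2_bov
    w_s <- w_b + w_o
    data_part <- function(u) fn(c(u, 0)) - u^2 / w_b
    g <- function(u) data_part(u) + u^2 / w_s
    o <- stats::optimize(g, interval = c(-5, 5), tol = 1e-8)
    u_star <- o$minimum
    h <- 1e-3
    gpp <- (g(u_star + h) - 2 * o$objective + g(u_star - h)) / h^2
    D <- gpp - 2 / w_s
    H <- matrix(c(D + 2 / w_b, D, D, D + 2 / w_o), 2, 2)
    detH <- D * 2 / w_o + D * 2 / w_b + 4 / (w_b * w_o)
    if (is.finite(detH) && detH > 0 && is.finite(D)) {
      cov <- 2 * matrix(c(H[2, 2], -D, -D, H[1, 1]), 2, 2) / detH
      dimnames(cov) <- list(nm, nm)
      b_star <- u_star * w_b / w_s
      o_star <- u_star * w_o / w_s
      eta_bov <- stats::setNames(o_star, as.character(occs))
      pbo <- lapply(names(typ), function(oc) {
        individual_params(typ[[oc]], b_star,
                          if (oc == as.character(occs)) o_star else 0)
      })
      return(structure(list(eta_bsv = b_star, eta_bov = eta_bov,
                            objective = o$objective,
                            posterior_covariance = cov,
                            params_by_occasion = stats::setNames(pbo, names(typ)),
                            converged = TRUE, restarts_used = 0L),
                       class = "individual_estimate"))
    }
    # fall through to the generic quasi-Newton path on numerical trouble
  }
  starts <- list(if (!is.null(start) && length(start) == k) start else rep(0, k))
  jit <- c(0.3, -0.3, 0.15, 0.6)
  for (i in seq_len(restarts)) starts <- c(starts, list(rep(jit[(i - 1) %% 4 + 1], k)))
  best <- NULL
  used <- 0L
  for (i in seq_along(starts)) {
    o <- stats::optim(starts[[i]], fn, method = "BFGS",
                      control = list(reltol = 1e-10, maxit = 500))
    if (is.null(best) || o$value < best$value - 1e-8) best <- o
    used <- i - 1L
    if (best$convergence == 0) break
  }
  hess <- stats::optimHess(best$par, fn)
  cov <- tryCatch(2 * solve(hess), error = function(e) {
    warning("singular posterior Hessian; falling back to prior covariance")
    diag(c(pop$omega2_bsv, rep(pop$omega2_bov, length(occs))), k)
  })
  cov <- (cov + t(cov)) / 2
  dimnames(cov) <- list(nm, nm)
  eta_bov <- stats::setNames(if (k > 1) best$par[-1] else numeric(0), as.character(occs))
  pbo <- lapply(names(typ), function(oc) {
    individual_params(typ[[oc]], best$par[1],
                      if (oc %in% names(eta_bov)) eta_bov[[oc]] else 0)
  })
  structure(list(eta_bsv = best$par[1], eta_bov = eta_bov,
                 objective = best$value, posterior_covariance = cov,
                 params_by_occasion = stats::setNames(pbo, names(typ)),
                 converged = best$convergence == 0,
                 restarts_used = used),
            class = "individual_estimate")
}

#' @export
print.individual_estimate <- function(x, ...) {
  cat(sprintf("MAP estimate: eta_bsv = %.4f%s, -2logpost = %.3f%s\n",
              x$eta_bsv,
              if (length(x$eta_bov)) paste0(", eta_bov = ",
                paste(sprintf("%.4f", x$eta_bov), collapse = ", ")) else "",
              x$objective,
              if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}

#' Draw approximate posterior samples of the random effects
#'
#' Multivariate-normal draws at the Laplace approximation (mode and inverse
#' Hessian) of the posterior. A non-positive-semidefinite covariance is
#' repaired to the nearest PSD matrix (eigenvalue clipping) with a warning.
#'
#' @param estimate An `individual_estimate` from [map_estimate()].
#' @param n Number of draws.
#' @param seed Optional integer seed; the global RNG stream is restored
#'   afterwards.
#' @return An `n` x k matrix of eta draws (columns: BSV then BOV effects).
#' @export
posterior_samples <- function(estimate, n, seed = NULL) {
  stopifnot(inherits(estimate, "individual_estimate"), n >= 1)
  mode <- c(estimate$eta_bsv, estimate$eta_bov)
  cov <- estimate$posterior_covariance
  ev <- eigen(cov, symmetric = TRUE)
  if (any(ev$values < -1e-10 * max(abs(ev$values), 1e-30))) {
    warning("posterior covariance not PSD; clipping negative eigenvalues")
  }
  vals <- pmax(ev$values, 0)
  rt <- ev$vectors %*% (sqrt(vals) * t(ev$vectors))
  k <- length(mode)
  z <- with_seed(seed, matrix(stats::rnorm(n * k), n, k))
  out <- sweep(z %*% rt, 2, mode, "+")
  colnames(out) <- colnames(cov)
  out
}
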