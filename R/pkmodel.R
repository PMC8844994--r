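#' Hill maturation of clearance with postmenstrual age
#'
#' Sigmoid maturation function `pma^hill / (pma^hill + mat50^hill)`,
#' strictly increasing in `pma` and equal to 0.5 at `pma == mat50`.
#' Evaluated as `1 / (1 + (mat50/pma)^hill)` for numerical stability at
#' large ages.
#'
#' @param pma Postmenstrual age in days (> 0); vectorized.
#' @param hill Hill coefficient (> 0).
#' @param mat50 PMA at 50% maturation, days (> 0).
#' @return Maturation fraction in (0, 1).
#' @export
maturation <- function(pma, hill, mat50) {
  if (any(!is.finite(pma)) || any(pma <= 0)) stop("pma must be positive")
  stopifnot(hill > 0, mat50 > 0)
  1 / (1 + exp(hill * (log(mat50) - log(pma))))
}

#' Alternative maturation functions for model comparison
#'
#' Simpler maturation shapes used only in goodness-of-fit comparisons
#' against the Hill function:
#' \describe{
#'   \item{linear}{`a + b * pma`, clipped to (0, 1].}
#'   \item{exponential}{`a * exp(b * pma)`, clipped to (0, 1].}
#'   \item{first_order}{`1 - exp(-k * pma)`, asymptoting at 1.}
#' }
#'
#' @param pma Postmenstrual age in days (> 0); vectorized.
#' @param kind One of `"linear"`, `"exponential"`, `"first_order"`.
#' @param params Named list of the parameters of the chosen form
#'   (`a`, `b` for linear/exponential; `k` for first_order).
#' @return Maturation fraction in (0, 1].
#' @export
alternative_maturation <- function(pma, kind = c("linear", "exponential", "first_order"),
                                   params) {
  if (any(!is.finite(pma)) || any(pma <= 0)) stop("pma must be positive")
  kind <- match.arg(kind)
  eps <- 1e-6
  f <- switch(kind,
    linear = params$a + params$b * pma,
    exponential = params$a * exp(params$b * pma),
    first_order = -expm1(-params$k * pma)
  )
  pmin(pmax(f, eps), 1)
}

#' Individual-typical PK parameters from covariates
#'
#' Applies the covariate model to the population typical values:
#' \deqn{CL = TVCL (WT/WT_{ref})^{0.75} F_{mat}(PMA) (SCr_{ref}/SCr)^{\theta_{SCr}}}
#' \deqn{Q = TVQ (WT/WT_{ref})^{0.75}, \quad V_c = TVV_c (WT/WT_{ref}), \quad V_p = TVV_p (WT/WT_{ref})}
#'
#' @param wt Body weight, kg (> 0).
#' @param pma Postmenstrual age, days (> 0).
#' @param scr Serum creatinine, umol/L (> 0).
#' @param pop A [pop_params()] object.
#' @return A `pk_params` object with fields `cl`, `vc`, `q`, `vp` (L/h, L).
#' @export
typical_params <- function(wt, pma, scr, pop) {
  stopifnot(inherits(pop, "pop_params"))
  if (!all(is.finite(c(wt, pma, scr))) || any(c(wt, pma, scr) <= 0)) {
    stop("covariates wt, pma, scr must be positive")
  }
  wr <- wt / pop$wt_ref
  pk_params(
    cl = pop$tvcl * wr^pop$wt_exp_cl_q * maturation(pma, pop$hill, pop$mat50) *
      (pop$scr_ref / scr)^pop$scr_exponent,
    vc = pop$tvvc * wr^pop$wt_exp_v,
    q  = pop$tvq * wr^pop$wt_exp_cl_q,
    vp = pop$tvvp * wr^pop$wt_exp_v
  )
}

#' Construct a set of individual PK parameters
#'
#' @param cl Clearance, L/h.
#' @param vc Central volume, L.
#' @param q Intercompartmental clearance, L/h (0 collapses the model to one
#'   compartment).
#' @param vp Peripheral volume, L.
#' @return A `pk_params` object.
#' @export
pk_params <- function(cl, vc, q, vp) {
  if (!all(is.finite(c(cl, vc, q, vp))) || cl <= 0 || vc <= 0 || q < 0 || vp <= 0) {
    stop("pk parameters must be positive (q may be zero)")
  }
  structure(list(cl = cl, vc = vc, q = q, vp = vp), class = "pk_params")
}

#' Apply log-normal random effects on clearance
#'
#' Clearance is scaled by `exp(eta_bsv + eta_bov)`; volumes and Q carry no
#' random effects in this model.
#'
#' @param typical A `pk_params` object of covariate-typical values.
#' @param eta_bsv Between-subject log-scale deviation.
#' @param eta_bov Between-occasion log-scale deviation.
#' @return A `pk_params` object.
#' @export
individual_params <- function(typical, eta_bsv = 0, eta_bov = 0) {
  stopifnot(inherits(typical, "pk_params"), is.finite(eta_bsv), is.finite(eta_bov))
  pk_params(cl = typical$cl * exp(eta_bsv + eta_bov),
            vc = typical$vc, q = typical$q, vp = typical$vp)
}

# hybrid rate constants of the 2-cmt model; beta computed as product/alpha
# to avoid cancellation. q = 0 degenerates cleanly to (alpha = k10, beta = 0).
pk_hybrid <- function(params) {
  k10 <- params$cl / params$vc
  k12 <- params$q / params$vc
  k21 <- params$q / params$vp
  s <- k10 + k12 + k21
  p <- k10 * k21
  disc <- max(s^2 - 4 * p, 0)
  alpha <- (s + sqrt(disc)) / 2
  beta <- if (alpha > 0) p / alpha else 0
  list(k10 = k10, k12 = k12, k21 = k21, alpha = alpha, beta = beta)
}

# (1 - exp(-lam * tau)) / lam, elementwise in tau, stable for small/zero lam
.phi <- function(lam, tau) {
  if (lam < 1e-12) tau else -expm1(-lam * tau) / lam
}

# int_0^tau u exp(-lam u) du = (1 - exp(-lam tau)(1 + lam tau)) / lam^2
.psi <- function(lam, tau) {
  if (lam < 1e-12) tau^2 / 2 else (1 - exp(-lam * tau) * (1 + lam * tau)) / lam^2
}

# unit-rate infusion responses (amounts per unit infusion rate) for both
# compartments at elapsed times tau >= 0 since infusion start (tau may be
# a vector or matrix). Repeated hybrid roots (relative gap < 1e-10) use
# the analytic limit.
.infusion_units <- function(h, tau) {
  tau[tau < 0] <- 0
  a <- h$alpha; b <- h$beta; k21 <- h$k21; k12 <- h$k12
  if (a - b < 1e-10 * a) {
    u1 <- .phi(a, tau) + (k21 - a) * .psi(a, tau)
    u2 <- k12 * .psi(a, tau)
  } else {
    pa <- .phi(a, tau)
    pb <- .phi(b, tau)
    u1 <- ((a - k21) * pa + (k21 - b) * pb) / (a - b)
    u2 <- k12 * (pb - pa) / (a - b)
  }
  list(u1 = u1, u2 = u2)
}

# amounts in central/peripheral compartments at times t for a dose table
# (columns time, amount, duration), by superposition; a finite infusion is
# an infinite infusion minus the same infusion delayed by its duration.
# Vectorized as a times x doses matrix.
compartment_amounts <- function(t, doses, params) {
  h <- pk_hybrid(params)
  rate <- doses$amount / doses$duration
  tau_on <- outer(t, doses$time, "-")
  tau_off <- tau_on - rep(doses$duration, each = length(t))
  on <- .infusion_units(h, tau_on)
  off <- .infusion_units(h, tau_off)
  list(central = drop((on$u1 - off$u1) %*% rate),
       peripheral = drop((on$u2 - off$u2) %*% rate))
}

#' Serum concentration under superposed constant-rate infusions
#'
#' Analytic biexponential solution of the two-compartment model with
#' first-order elimination under any sequence of constant-rate infusions.
#' Zero before the first dose, continuous at infusion boundaries; the
#' degenerate equal-roots case is evaluated by its analytic limit, and
#' `q = 0` reduces exactly to the one-compartment infusion equation.
#'
#' @param t Times, hours (vectorized).
#' @param doses A data.frame with columns `time` (h), `amount` (mg) and
#'   `duration` (h).
#' @param params A `pk_params` object.
#' @return Central-compartment concentration, mg/L, at each `t`.
#' @export
concentration <- function(t, doses, params) {
  stopifnot(inherits(params, "pk_params"),
            all(c("time", "amount", "duration") %in% names(doses)))
  if (nrow(doses) > 0 &&
      (any(doses$amount <= 0) || any(doses$duration <= 0) || any(doses$time < 0))) {
    stop("doses must have positive amount and duration and non-negative time")
  }
  if (any(t < 0)) stop("t must be non-negative")
  if (nrow(doses) == 0) return(numeric(length(t)))
  compartment_amounts(t, doses, params)$central / params$vc
}

#' Steady-state concentration profile of a repeated regimen
#'
#' Superposes doses until the accumulation series has converged (relative
#' tail below 1e-10, driven by the terminal hybrid rate constant), then
#' exposes the within-interval profile. The trough is taken at the end of
#' the dosing interval and the peak at the end of the infusion.
#'
#' @param reg A [regimen()] object.
#' @param params A `pk_params` object.
#' @return A list with `conc` (a function of time-within-interval, hours),
#'   `trough` and `peak` (mg/L), and the input `regimen`.
#' @export
steady_state_profile <- function(reg, params) {
  stopifnot(inherits(reg, "regimen"), inherits(params, "pk_params"))
  h <- pk_hybrid(params)
  lam <- if (h$beta > 0) h$beta else h$alpha
  n <- min(max(ceiling(23.03 / (lam * reg$interval)) + 1, 5), 20000)
  doses <- data.frame(time = (seq_len(n) - 1) * reg$interval,
                      amount = reg$dose, duration = reg$infusion_duration)
  t0 <- (n - 1) * reg$interval
  conc <- function(t) concentration(t0 + t, doses, params)
  list(conc = conc,
       trough = conc(reg$interval),
       peak = conc(reg$infusion_duration),
       regimen = reg)
}

#' Steady-state 24-hour area under the curve
#'
#' For linear PK, the steady-state AUC over 24 h equals the daily dose
#' divided by clearance: `(24 / interval) * dose / cl`.
#'
#' @param reg A [regimen()] object.
#' @param params A `pk_params` object.
#' @return AUC over 24 h at steady state, mg.h/L.
#' @export
auc24_ss <- function(reg, params) {
  stopifnot(inherits(reg, "regimen"), inherits(params, "pk_params"))
  (24 / reg$interval) * reg$dose / params$cl
}

#' Residual-error standard deviation
#'
#' Combined proportional-additive model:
#' `sqrt((sigma_prop * pred)^2 + sigma_add^2)`.
#'
#' @param pred Model-predicted concentration, mg/L (>= 0, vectorized).
#' @param sigma_prop Proportional error fraction.
#' @param sigma_add Additive error SD, mg/L.
#' @return Standard deviation, mg/L.
#' @export
residual_sd <- function(pred, sigma_prop, sigma_add) {
  if (any(pred < 0)) stop("pred must be non-negative")
  sqrt((sigma_prop * pred)^2 + sigma_add^2)
}

#' Dosing regimen
#'
#' @param dose Dose amount per administration, mg.
#' @param interval Dosing interval, hours.
#' @param infusion_duration Infusion duration, hours (defaults to 1 h; must
#'   not exceed the interval).
#' @param n_doses Number of doses, or `NA` for a steady-state regimen.
#' @return A `regimen` object.
#' @export
regimen <- function(dose, interval, infusion_duration = 1, n_doses = NA) {
  if (!is.finite(dose) || dose <= 0) stop("dose must be positive")
  if (!is.finite(interval) || interval <= 0) stop("interval must be positive")
  if (!is.finite(infusion_duration) || infusion_duration <= 0 ||
      infusion_duration > interval) {
    stop("infusion_duration must be in (0, interval]")
  }
  structure(list(dose = dose, interval = interval,
                 infusion_duration = infusion_duration, n_doses = n_doses),
            class = "regimen")
}

#' @export
print.regimen <- function(x, ...) {
  cat(sprintf("regimen: %.4g mg q%gh over %g h%s\n", x$dose, x$interval,
              x$infusion_duration,
              if (is.na(x$n_doses)) " (steady state)" else sprintf(", %d doses", x$n_doses)))
  invisible(x)
}
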