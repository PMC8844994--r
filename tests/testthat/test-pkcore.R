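# Structural model: maturation, covariate model, random effects,
# analytic two-compartment infusion solution, steady state, AUC24,
# residual error.

test_that("Hill maturation is half-maximal at mat50, monotone, and matches
           an independent high-precision evaluation", {
  expect_equal(maturation(197, 7.02, 197), 0.5)
  # frozen value computed independently at 40-digit precision
  expect_equal(maturation(236, 7.02, 197), 0.780401747415993, tolerance = 1e-12)
  expect_lt(abs(maturation(1e7, 7.02, 197) - 1), 1e-6)
  pma <- seq(120, 500, by = 2)
  expect_true(all(diff(maturation(pma, 7.02, 197)) > 0))
  expect_error(maturation(0, 7.02, 197), "positive")
  expect_error(maturation(-5, 7.02, 197), "positive")
})

test_that("alternative maturation shapes behave at their limits", {
  expect_equal(alternative_maturation(1e9, "first_order", list(k = 0.01)), 1)
  expect_equal(alternative_maturation(c(100, 200, 300), "linear",
                                      list(a = 0.4, b = 0)),
               rep(0.4, 3))
  # exponential form at a fixture point: 0.2 * exp(0.004 * 250)
  expect_equal(alternative_maturation(250, "exponential",
                                      list(a = 0.2, b = 0.004)),
               0.2 * exp(1), tolerance = 1e-12)
  expect_true(alternative_maturation(1e6, "exponential",
                                     list(a = 0.2, b = 0.004)) <= 1)
  expect_error(alternative_maturation(100, "hyperbolic", list()), "arg")
})

test_that("covariate model scales clearance and volumes with the fixed
           allometric exponents and the SCr power term", {
  pop <- table3_pop()
  # reference subject at full maturation recovers the typical values
  p_ref <- typical_params(pop$wt_ref, 1e6, pop$scr_ref, pop)
  expect_equal(p_ref$cl, pop$tvcl, tolerance = 1e-6)
  expect_equal(p_ref$vc, pop$tvvc)
  p1 <- typical_params(1.5, 250, 42, pop)
  p2 <- typical_params(3.0, 250, 42, pop)
  expect_equal(p2$cl / p1$cl, 2^0.75)
  expect_equal(p2$q / p1$q, 2^0.75)
  expect_equal(p2$vc / p1$vc, 2)
  expect_equal(p2$vp / p1$vp, 2)
  # doubling SCr scales CL by 2^-0.541
  p3 <- typical_params(1.5, 250, 84, pop)
  expect_equal(p3$cl / p1$cl, 2^-pop$scr_exponent)
  # frozen composite fixture: independent formula evaluation
  p4 <- typical_params(1.68, 236, 42, pop)
  expect_equal(p4$cl, 0.140 * 1.68^0.75 * 0.780401747415993, tolerance = 1e-10)
  expect_equal(p4$vc, 0.769 * 1.68)
  expect_error(typical_params(-1, 236, 42, pop), "positive")
})

test_that("random effects act on clearance only and the CV <-> omega^2
           conversion round-trips", {
  typ <- ref_params()
  expect_equal(unclass(individual_params(typ, 0, 0)), unclass(typ))
  up <- individual_params(typ, log(2), 0)
  expect_equal(up$cl, 2 * typ$cl)
  expect_equal(up$vc, typ$vc)
  expect_equal(cv_to_omega2(0.123), log(1 + 0.123^2))
  for (cv in c(0.01, 0.123, 0.133, 0.5, 1.2)) {
    expect_equal(omega2_to_cv(cv_to_omega2(cv)), cv, tolerance = 1e-12)
  }
})

test_that("residual error model is combined proportional-additive", {
  expect_equal(residual_sd(0, 0.168, 1.76), 1.76)
  expect_equal(residual_sd(10, 0.168, 1.76), 2.43310501211929, tolerance = 1e-12)
  preds <- seq(0, 60, by = 0.5)
  expect_true(all(diff(residual_sd(preds, 0.168, 1.76)) >= 0))
  expect_error(residual_sd(-1, 0.168, 1.76), "non-negative")
})

test_that("concentration is zero before dosing, continuous at infusion
           boundaries, and reduces to one compartment as q -> 0", {
  p <- ref_params()
  doses <- make_doses(n = 3)
  expect_equal(concentration(c(0, 0), doses[-(1:3), ], p), c(0, 0))
  expect_equal(concentration(0, doses, p), 0)
  # continuity at start and end of an infusion
  eps <- 1e-9
  for (tt in c(8, 9)) {
    expect_equal(concentration(tt - eps, doses, p),
                 concentration(tt + eps, doses, p), tolerance = 1e-6)
  }
  # q = 0: closed-form one-compartment infusion equation
  p1 <- pk_params(cl = 0.16, vc = 1.3, q = 0, vp = 0.5)
  k10 <- p1$cl / p1$vc
  one_cmt <- function(t, d) {
    rate <- d$amount / d$duration
    ifelse(t <= d$time, 0,
      ifelse(t <= d$time + d$duration,
        rate / p1$cl * (1 - exp(-k10 * (t - d$time))),
        rate / p1$cl * (1 - exp(-k10 * d$duration)) *
          exp(-k10 * (t - d$time - d$duration))))
  }
  d1 <- data.frame(time = 0, amount = 20, duration = 1)
  tt <- c(0.2, 0.5, 1, 1.0001, 3, 9, 30)
  expect_equal(concentration(tt, d1, p1), one_cmt(tt, d1), tolerance = 1e-10)
})

test_that("analytic solution matches adaptive ODE integration to 1e-6
           over randomized parameters and regimens", {
  skip_if_not_installed("deSolve")
  set.seed(42)
  for (i in 1:12) {
    p <- pk_params(cl = runif(1, 0.02, 0.5), vc = runif(1, 0.3, 3),
                   q = runif(1, 0, 0.6), vp = runif(1, 0.1, 1.5))
    nd <- sample(1:5, 1)
    tau <- sample(c(6, 8, 12, 24), 1)
    doses <- data.frame(time = (seq_len(nd) - 1) * tau,
                        amount = runif(1, 5, 60),
                        duration = runif(1, 0.5, 2))
    tt <- sort(runif(7, 0, nd * tau + 12))
    a <- concentration(tt, doses, p)
    o <- ode_oracle(tt, doses, p)
    expect_lt(max(abs(a - o) / pmax(abs(o), 1e-6)), 1e-6)
  }
})

test_that("mass balance holds without elimination and the degenerate
           equal-root case is finite and accurate", {
  # cl = 0 variant: all infused drug stays in the two compartments
  p0 <- pk_params(cl = 1e-300, vc = 1.3, q = 0.2, vp = 0.5)
  p0$cl <- 0 # construct the no-elimination limit directly
  doses <- make_doses(n = 2, amount = 10, interval = 8, duration = 2)
  amt <- neovanc:::compartment_amounts(c(1, 5, 9, 12, 40), doses, p0)
  infused <- c(5, 10, 15, 20, 20)
  expect_equal(amt$central + amt$peripheral, infused, tolerance = 1e-9)
  # equal hybrid roots: k10 = k21 and k12 = 0 makes alpha == beta
  pe <- pk_params(cl = 0.2, vc = 1, q = 1e-22, vp = 5e-22)
  d1 <- data.frame(time = 0, amount = 10, duration = 1)
  ce <- concentration(c(0.5, 1, 4), d1, pe)
  expect_true(all(is.finite(ce)))
  pn <- pk_params(cl = 0.2, vc = 1, q = 0, vp = 1)
  expect_equal(ce, concentration(c(0.5, 1, 4), d1, pn), tolerance = 1e-4)
})

test_that("steady-state profile agrees with brute-force superposition,
           orders trough < peak, and is linear in dose", {
  p <- ref_params()
  reg <- regimen(23.5, 8, 1)
  ss <- steady_state_profile(reg, p)
  expect_lt(ss$trough, ss$peak)
  # brute force: superpose 30 terminal half-lives of doses
  h <- neovanc:::pk_hybrid(p)
  n <- ceiling(30 * log(2) / h$beta / reg$interval)
  doses <- data.frame(time = (seq_len(n) - 1) * reg$interval,
                      amount = reg$dose, duration = reg$infusion_duration)
  t0 <- (n - 1) * reg$interval
  for (tt in c(1, 3, 8)) {
    expect_equal(ss$conc(tt), concentration(t0 + tt, doses, p),
                 tolerance = 1e-6)
  }
  ss2 <- steady_state_profile(regimen(47, 8, 1), p)
  expect_equal(ss2$trough, 2 * ss$trough, tolerance = 1e-8)
  expect_equal(ss2$peak, 2 * ss$peak, tolerance = 1e-8)
})

test_that("steady-state AUC24 equals daily dose over clearance and matches
           trapezoidal integration of the profile", {
  p <- ref_params()
  reg <- regimen(42 * p$cl / 3, 8, 1) # daily dose = 42*cl/3*3
  expect_equal(auc24_ss(regimen(42, 24, 1),
                        pk_params(0.105, 1, 0.1, 0.3)), 400)
  ss <- steady_state_profile(reg, p)
  tt <- seq(0, reg$interval, length.out = 4001)
  cc <- ss$conc(tt)
  trap <- sum((cc[-1] + cc[-length(cc)]) / 2 * diff(tt)) * 24 / reg$interval
  expect_equal(auc24_ss(reg, p), trap, tolerance = 1e-3)
  # inverse proportionality in CL; independence of vc, q, vp
  p2 <- pk_params(2 * p$cl, p$vc, p$q, p$vp)
  expect_equal(auc24_ss(reg, p2), auc24_ss(reg, p) / 2)
  p3 <- pk_params(p$cl, 2 * p$vc, 3 * p$q, 0.5 * p$vp)
  expect_equal(auc24_ss(reg, p3), auc24_ss(reg, p))
})

test_that("regimen validation rejects non-physical inputs", {
  expect_error(regimen(-5, 8), "positive")
  expect_error(regimen(10, 8, infusion_duration = 9), "interval")
  expect_error(pk_params(0.1, -1, 0.1, 0.1), "positive")
})
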