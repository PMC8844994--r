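# Shared fixtures and independent oracles, built in code at test time.

table3_pop <- function(...) pop_params(...)

# a mid-cohort reference subject: ~34 wk PMA, 1.68 kg, SCr at reference
ref_params <- function(pop = table3_pop()) typical_params(1.68, 236, 42, pop)

# simple q8h course fixture
make_doses <- function(n = 6, amount = 23.5, interval = 8, duration = 1) {
  data.frame(time = (seq_len(n) - 1) * interval, amount = amount,
             duration = duration, occasion = 1L)
}

# minimal synthetic subject with given observations (covariates constant)
make_subject <- function(id = "S1", doses = make_doses(),
                         obs_time = numeric(0), obs_value = numeric(0),
                         blq = rep(FALSE, length(obs_time)),
                         wt = 1.68, scr = 42, pma0 = 236, truth = NULL) {
  times <- sort(unique(c(doses$time, obs_time)))
  cov <- data.frame(time = times, wt = wt, scr = scr,
                    pma = pma0 + times / 24)
  obs <- data.frame(time = obs_time, value = obs_value, blq = blq,
                    lloq = rep(1, length(obs_time)),
                    occasion = rep(1L, length(obs_time)))
  o <- order(obs$time); obs <- obs[o, , drop = FALSE]
  subject_record(id, doses, obs, cov, gestational_age = pma0 - 17,
                 truth = truth)
}

# independent ODE oracle for the two-compartment infusion model
ode_oracle <- function(t, doses, p) {
  testthat::skip_if_not_installed("deSolve")
  rate_at <- function(tt) {
    sum(ifelse(tt >= doses$time & tt < doses$time + doses$duration,
               doses$amount / doses$duration, 0))
  }
  k10 <- p$cl / p$vc; k12 <- p$q / p$vc
  k21 <- if (p$vp > 0) p$q / p$vp else 0
  f <- function(tt, y, parms) {
    list(c(rate_at(tt) - (k10 + k12) * y[1] + k21 * y[2],
           k12 * y[1] - k21 * y[2]))
  }
  tt <- sort(unique(c(0, t, doses$time, doses$time + doses$duration)))
  out <- deSolve::ode(c(0, 0), tt, f, NULL, rtol = 1e-11, atol = 1e-13)
  out[match(t, tt), 2] / p$vc
}

# dense grid-search oracle for the MAP mode (1 or 2 etas)
grid_map_oracle <- function(subject, pop, span = 0.8, n = 161) {
  occs <- sort(unique(subject$obs$occasion))
  k <- 1 + length(occs)
  g <- seq(-span, span, length.out = n)
  if (k == 1) {
    v <- vapply(g, function(e) neg2log_posterior(e, subject, pop), 0)
    return(list(etas = g[which.min(v)], value = min(v), step = g[2] - g[1]))
  }
  best <- NULL
  for (e1 in g) {
    v <- vapply(g, function(e2) neg2log_posterior(c(e1, e2), subject, pop), 0)
    j <- which.min(v)
    if (is.null(best) || v[j] < best$value) {
      best <- list(etas = c(e1, g[j]), value = v[j], step = g[2] - g[1])
    }
  }
  best
}

# cohort of 3 subjects exercising all three exclusion rules:
# E starts vancomycin at PNA 5 d -> excluded subject
# L has one observation 7.01 d after the last infusion start -> removed
# M has one mid-infusion sample -> removed
exclusion_cohort <- function() {
  sE <- make_subject("E", make_doses(n = 2), obs_time = c(7, 15),
                     obs_value = c(9, 8), pma0 = 200 + 5)
  sE$gestational_age <- 200
  sL <- make_subject("L", make_doses(n = 2),
                     obs_time = c(8 + 6.99 * 24, 8 + 7.01 * 24),
                     obs_value = c(2, 1.5), pma0 = 240)
  sM <- make_subject("M", make_doses(n = 2), obs_time = c(0.5, 7.9, 9),
                     obs_value = c(20, 7, 25), pma0 = 250)
  cohort(list(sE, sL, sM))
}
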