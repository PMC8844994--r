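# Population fitting (Laplace with interaction), likelihood-ratio
# p-values, bootstrap, conditional weighted residuals and the
# variance-explained metric.

test_that("chi-square LRT p-values match reference values and decrease in
           the OFV change", {
  expect_equal(round(lrt_pvalue(5.583, 2), 2), 0.06)
  expect_equal(lrt_pvalue(0, 2), 1)
  expect_equal(round(lrt_pvalue(3.841, 1), 2), 0.05)
  dofv <- seq(0.5, 20, by = 0.5)
  expect_true(all(diff(lrt_pvalue(dofv, 3)) < 0))
  expect_error(lrt_pvalue(3, 0), "df")
})

make_fit_cohort <- function(n, seed, design = list(trough_before_dose = c(2, 4),
                                                   peak_after_dose = 2)) {
  pop <- table3_pop()
  co <- generate_cohort(n, seed = seed)
  simulate_observations(co, pop, design = design, seed = seed + 1)
}

test_that("refitting data simulated at the initial values does not end up
           above the generating-value objective, and the fit reports
           sane uncertainty diagnostics", {
  pop <- table3_pop()
  co <- make_fit_cohort(25, seed = 501)
  fit <- nlme_fit(co, init = pop, estimate = c("tvcl", "omega_bsv"),
                  compute_se = TRUE, control = list(reltol = 1e-7))
  # OFV at the optimum is no worse than at the generating values
  ofv_truth <- nlme_fit(co, init = pop, estimate = c("tvcl"),
                        compute_se = FALSE,
                        control = list(maxit = 0))$ofv
  expect_lte(fit$ofv, ofv_truth + 1e-3)
  expect_true(fit$converged)
  # estimates near truth on this moderate cohort
  expect_lt(abs(log(fit$estimates$tvcl / pop$tvcl)), 0.15)
  expect_true(all(is.finite(fit$se)))
  expect_gte(fit$condition_number, 1)
  expect_lt(fit$condition_number, 1000)
  expect_true(is.finite(fit$shrinkage$bsv_pct))
  expect_lt(fit$shrinkage$bsv_pct, 100)
  expect_equal(nrow(fit$ebe_table), 25)
})

test_that("a single subject with rich low-noise data recovers its
           individual clearance within 5 percent", {
  pop <- pop_params(sigma_prop = 0.03, sigma_add = 0.1)
  doses <- make_doses(n = 8)
  eta_true <- 0.18
  p_true <- individual_params(ref_params(pop), eta_true)
  tt <- c(1, 4, 7.9, 9, 12, 15.9, 30, 41, 49, 52, 55.9, 60)
  s <- make_subject("R1", doses, obs_time = tt,
                    obs_value = pmax(concentration(tt, doses, p_true) *
                                       (1 + 0.02 * sin(seq_along(tt))), 0.2))
  est <- map_estimate(s, pop)
  cl_hat <- est$params_by_occasion[["1"]]$cl
  expect_lt(abs(cl_hat / p_true$cl - 1), 0.05)
})

test_that("bootstrap resampling is seed-reproducible and collapses to
           zero-width intervals on a cohort of identical subjects", {
  pop <- table3_pop()
  base <- make_fit_cohort(1, seed = 601)$subjects[[1]]
  subs <- lapply(1:8, function(i) { s <- base; s$subject_id <- paste0("T", i); s })
  co <- cohort(subs)
  b1 <- bootstrap_fit(co, n = 5, seed = 9, init = pop, estimate = "tvcl",
                      control = list(reltol = 1e-8))
  b2 <- bootstrap_fit(co, n = 5, seed = 9, init = pop, estimate = "tvcl",
                      control = list(reltol = 1e-8))
  expect_identical(b1$resample_indices, b2$resample_indices)
  expect_equal(b1$n_failed, 0)
  width <- b1$ci90["95%", "tvcl"] - b1$ci90["5%", "tvcl"]
  expect_lt(width / b1$means[["tvcl"]], 1e-3)
})

test_that("bootstrap on a small heterogeneous cohort brackets the
           generating clearance", {
  pop <- table3_pop()
  co <- make_fit_cohort(12, seed = 701)
  bs <- bootstrap_fit(co, n = 10, seed = 11, init = pop, estimate = "tvcl")
  expect_lte(bs$ci90["5%", "tvcl"], bs$means[["tvcl"]])
  expect_gte(bs$ci90["95%", "tvcl"], bs$means[["tvcl"]])
  # generating value inside (or extremely close to) the percentile interval
  expect_gt(bs$ci90["95%", "tvcl"], pop$tvcl * 0.8)
  expect_lt(bs$ci90["5%", "tvcl"], pop$tvcl * 1.25)
})

test_that("the population estimator is consistent: typical-clearance bias
           shrinks as the cohort grows", {
  pop <- table3_pop()
  bias_at <- function(n, seeds) {
    mean(vapply(seeds, function(sd) {
      co <- make_fit_cohort(n, seed = 1000 * n + sd)
      fit <- suppressWarnings(nlme_fit(co, init = pop, estimate = "tvcl",
                                       compute_se = FALSE))
      log(fit$estimates$tvcl / pop$tvcl)
    }, 0))
  }
  b50 <- abs(bias_at(50, 1:2))
  b200 <- abs(bias_at(200, 1:2))
  # either strictly closer to the truth than the small-cohort fit, or
  # already within the noise floor of the large-cohort estimator
  expect_true(b200 < b50 + 0.01 || b200 < 0.02)
  expect_lt(b200, 0.05)
})

test_that("conditional weighted residuals vanish for data at the
           conditional prediction and match a direct one-observation
           linearization", {
  pop <- table3_pop()
  doses <- make_doses(n = 4)
  typ <- ref_params(pop)
  s0 <- make_subject("W0", doses, obs_time = c(23.9, 25),
                     obs_value = concentration(c(23.9, 25), doses, typ))
  cw0 <- cwres(cohort(list(s0)), pop)
  expect_lt(max(abs(cw0$cwres)), 1e-3)
  # one-observation subject: direct scalar linearization oracle
  s1 <- make_subject("W1", doses, obs_time = 23.9, obs_value = 15)
  est <- map_estimate(s1, pop)
  mode <- c(est$eta_bsv, est$eta_bov)
  f <- neovanc:::subject_predictions(s1, pop, mode)
  d <- 1e-4
  g1 <- (neovanc:::subject_predictions(s1, pop, mode + c(d, 0)) -
         neovanc:::subject_predictions(s1, pop, mode - c(d, 0))) / (2 * d)
  g2 <- (neovanc:::subject_predictions(s1, pop, mode + c(0, d)) -
         neovanc:::subject_predictions(s1, pop, mode - c(0, d))) / (2 * d)
  v <- g1^2 * pop$omega2_bsv + g2^2 * pop$omega2_bov +
    residual_sd(f, pop$sigma_prop, pop$sigma_add)^2
  expected <- (15 - (f - g1 * mode[1] - g2 * mode[2])) / sqrt(v)
  cw1 <- cwres(cohort(list(s1)), pop)
  expect_equal(cw1$cwres, unname(expected), tolerance = 1e-6)
})

test_that("under the null about five percent of conditional weighted
           residuals exceed 1.96 in absolute value", {
  pop <- table3_pop()
  co <- make_fit_cohort(120, seed = 801,
                        design = list(trough_before_dose = c(2, 4),
                                      peak_after_dose = c(2, 4)))
  cw <- cwres(co, pop)
  frac <- mean(abs(cw$cwres) > 1.96)
  expect_gt(frac, 0.02)
  expect_lt(frac, 0.09)
})

test_that("the variance-explained metric is zero for no covariates,
           complete in the no-random-effects limit, and lands in the
           reported range on a calibrated cohort", {
  pop <- table3_pop()
  co <- generate_cohort(400, seed = 901)
  expect_equal(variance_explained(co, pop, character(0)), 0)
  pop0 <- pop_params(cv_bsv = 1e-9, cv_bov = 1e-9)
  expect_equal(variance_explained(co, pop0, c("wt", "pma", "scr")), 100,
               tolerance = 1e-4)
  ve_all <- variance_explained(co, pop, c("wt", "pma", "scr"))
  expect_gt(ve_all, 70)
  expect_lt(ve_all, 95)
  ve_wt <- variance_explained(co, pop, "wt")
  expect_gt(ve_all, ve_wt)
  expect_error(variance_explained(co, pop, "height"), "unknown")
})
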