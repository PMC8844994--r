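#' Convert a coefficient of variation to a log-scale variance
#'
#' For a log-normally distributed quantity with coefficient of variation
#' `cv` (as a fraction, e.g. 0.123 for 12.3%), the variance of its natural
#' logarithm is `log(1 + cv^2)`.
#'
#' @param cv Coefficient of variation as a fraction (> 0 allowed to be 0).
#' @return Log-scale variance (omega^2).
#' @seealso [omega2_to_cv()]
#' @export
cv_to_omega2 <- function(cv) {
  stopifnot(is.numeric(cv), all(cv >= 0))
  log(1 + cv^2)
}

#' Convert a log-scale variance to a coefficient of variation
#'
#' Inverse of [cv_to_omega2()]: `cv = sqrt(exp(omega2) - 1)`.
#'
#' @param omega2 Log-scale variance (>= 0).
#' @return Coefficient of variation as a fraction.
#' @export
omega2_to_cv <- function(omega2) {
  stopifnot(is.numeric(omega2), all(omega2 >= 0))
  sqrt(exp(omega2) - 1)
}

#' Population pharmacokinetic parameters
#'
#' Container for the fixed effects, random-effect variances, residual-error
#' terms and covariate reference values of the neonatal vancomycin model.
#' Defaults are the final-model estimates: a two-compartment infusion model
#' with allometric weight scaling (exponents 0.75 on clearances, 1 on
#' volumes), a Hill maturation function of postmenstrual age on clearance,
#' and a serum-creatinine power term on clearance. Between-subject (BSV)
#' and between-occasion (BOV) variability act on clearance only and are
#' log-normal; residual error is combined proportional-additive.
#'
#' @param tvcl Typical clearance at the reference covariates, L/h.
#' @param tvvc Typical central volume, L (per `wt_ref` kg).
#' @param tvq Typical intercompartmental clearance, L/h.
#' @param tvvp Typical peripheral volume, L.
#' @param hill Hill coefficient of the maturation function (dimensionless).
#' @param mat50 Postmenstrual age at 50% maturation of clearance, days.
#' @param scr_exponent Exponent of the serum-creatinine power term.
#' @param wt_exp_cl_q Allometric exponent on CL and Q (fixed at 0.75).
#' @param wt_exp_v Allometric exponent on Vc and Vp (fixed at 1).
#' @param cv_bsv Between-subject CV of clearance (fraction).
#' @param cv_bov Between-occasion CV of clearance (fraction).
#' @param sigma_prop Proportional residual error (fraction).
#' @param sigma_add Additive residual error, mg/L.
#' @param wt_ref Reference body weight, kg.
#' @param scr_ref Reference serum creatinine, umol/L.
#' @return An object of class `pop_params`. Log-scale variances
#'   `omega2_bsv` and `omega2_bov` are derived via [cv_to_omega2()].
#' @examples
#' pop <- pop_params()
#' pop$tvcl
#' @export
pop_params <- function(tvcl = 0.140, tvvc = 0.769, tvq = 0.147, tvvp = 0.285,
                       hill = 7.02, mat50 = 197, scr_exponent = 0.541,
                       wt_exp_cl_q = 0.75, wt_exp_v = 1,
                       cv_bsv = 0.123, cv_bov = 0.133,
                       sigma_prop = 0.168, sigma_add = 1.76,
                       wt_ref = 1, scr_ref = 42) {
  vals <- c(tvcl = tvcl, tvvc = tvvc, tvq = tvq, tvvp = tvvp, hill = hill,
            mat50 = mat50, scr_exponent = scr_exponent,
            sigma_prop = sigma_prop, sigma_add = sigma_add,
            wt_ref = wt_ref, scr_ref = scr_ref)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all population parameters must be finite and strictly positive")
  }
  if (cv_bsv < 0 || cv_bov < 0) stop("CV terms must be non-negative")
  structure(list(
    tvcl = tvcl, tvvc = tvvc, tvq = tvq, tvvp = tvvp,
    hill = hill, mat50 = mat50, scr_exponent = scr_exponent,
    wt_exp_cl_q = wt_exp_cl_q, wt_exp_v = wt_exp_v,
    cv_bsv = cv_bsv, cv_bov = cv_bov,
    omega2_bsv = cv_to_omega2(cv_bsv), omega2_bov = cv_to_omega2(cv_bov),
    sigma_prop = sigma_prop, sigma_add = sigma_add,
    wt_ref = wt_ref, scr_ref = scr_ref
  ), class = "pop_params")
}

#' @export
print.pop_params <- function(x, ...) {
  cat("Population PK parameters (2-cmt infusion, CL random effects)\n")
  cat(sprintf("  TVCL %.4g L/h, TVVc %.4g L, TVQ %.4g L/h, TVVp %.4g L\n",
              x$tvcl, x$tvvc, x$tvq, x$tvvp))
  cat(sprintf("  Hill %.4g, Mat50 %.4g d, SCr exponent %.4g\n",
              x$hill, x$mat50, x$scr_exponent))
  cat(sprintf("  CV(BSV) %.1f%%, CV(BOV) %.1f%%, sigma_prop %.1f%%, sigma_add %.3g mg/L\n",
              100 * x$cv_bsv, 100 * x$cv_bov, 100 * x$sigma_prop, x$sigma_add))
  cat(sprintf("  references: WT %.3g kg, SCr %.3g umol/L; allometric exponents %.3g / %.3g\n",
              x$wt_ref, x$scr_ref, x$wt_exp_cl_q, x$wt_exp_v))
  invisible(x)
}

# keys used in the flat YAML serialization (mirror the published symbols)
.pop_yaml_keys <- c(
  TVCL = "tvcl", TVVc = "tvvc", TVQ = "tvq", TVVp = "tvvp",
  theta_PMA_CL_Hill = "hill", theta_PMA_CL_Mat50 = "mat50",
  theta_SCr_CL = "scr_exponent",
  theta_WT_CL_Q = "wt_exp_cl_q", theta_WT_V = "wt_exp_v",
  CVCL = "cv_bsv", CVCL_BOV = "cv_bov",
  sigma_prop = "sigma_prop", sigma_add = "sigma_add",
  WT_ref = "wt_ref", SCr_ref = "scr_ref"
)

#' Read population parameters from a YAML config file
#'
#' The file is a flat mapping whose keys mirror the published parameter
#' symbols (`TVCL`, `theta_PMA_CL_Hill`, `theta_PMA_CL_Mat50`,
#' `theta_SCr_CL`, `TVVc`, `TVQ`, `TVVp`, `CVCL`, `CVCL_BOV`, `sigma_prop`,
#' `sigma_add`, `WT_ref`, `SCr_ref`). CVs are fractions. Missing keys fall
#' back to the defaults of [pop_params()].
#'
#' @param path Path to a YAML file.
#' @return A `pop_params` object.
#' @export
read_pop_params <- function(path) {
  if (!file.exists(path)) stop("model parameter file not found: ", path)
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), names(.pop_yaml_keys))
  if (length(unknown)) stop("unknown model parameter keys: ",
                            paste(unknown, collapse = ", "))
  args <- stats::setNames(raw, .pop_yaml_keys[names(raw)])
  do.call(pop_params, lapply(args, as.numeric))
}

#' Write population parameters to a YAML config file
#'
#' @param pop A `pop_params` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pop_params <- function(pop, path) {
  stopifnot(inherits(pop, "pop_params"))
  out <- lapply(.pop_yaml_keys, function(f) pop[[f]])
  yaml::write_yaml(out, path)
  invisible(path)
}

# evaluate an expression with a temporary, restorable RNG state; seed = NULL
# leaves the global stream untouched
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
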