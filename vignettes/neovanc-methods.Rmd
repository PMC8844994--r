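---
title: "Model-based dosing of intravenous vancomycin in neonates: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based dosing of intravenous vancomycin in neonates: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neovanc)
```

## The model

Serum vancomycin kinetics in NICU neonates are described by a
two-compartment model with constant-rate infusion input and first-order
elimination. For a subject with body weight $WT$ (kg), postmenstrual age
$PMA$ (days) and serum creatinine $SCr$ (µmol/L), the covariate-typical
parameters are

$$CL = TVCL \cdot \left(\frac{WT}{WT_{ref}}\right)^{0.75} \cdot
  \frac{PMA^{H}}{PMA^{H} + Mat_{50}^{H}} \cdot
  \left(\frac{SCr_{ref}}{SCr}\right)^{\theta_{SCr}}, \qquad
  Q = TVQ \cdot \left(\frac{WT}{WT_{ref}}\right)^{0.75},$$

$$V_c = TVV_c \cdot \frac{WT}{WT_{ref}}, \qquad
  V_p = TVV_p \cdot \frac{WT}{WT_{ref}},$$

with the allometric exponents fixed at 0.75 (clearances) and 1 (volumes).
The Hill term describes postnatal maturation of glomerular filtration on
the PMA scale: it is 0.5 exactly at $PMA = Mat_{50}$ and approaches 1 in
infancy. Alternative maturation shapes (linear, exponential, first-order)
are provided only for goodness-of-fit comparison; in the source analysis
they all fit substantially worse.

Between-subject (BSV) and between-occasion (BOV) variability act on $CL$
only, log-normally: $CL_i = CL \cdot e^{\eta_{i}^{BSV} + \eta_{ik}^{BOV}}$.
Coefficients of variation relate to log-scale variances by
$CV = \sqrt{e^{\omega^2}-1}$. Residual error is combined
proportional–additive, $sd(y \mid f) = \sqrt{(\sigma_{prop} f)^2 +
\sigma_{add}^2}$.

The shipped default parameter set (`pop_params()`,
`inst/extdata/model_params.yaml`) is: TVCL 0.140 L/h, $H$ 7.02,
$Mat_{50}$ 197 d, $\theta_{SCr}$ 0.541, TVV$_c$ 0.769 L, TVQ 0.147 L/h,
TVV$_p$ 0.285 L, CV(BSV) 12.3%, CV(BOV) 13.3%, $\sigma_{prop}$ 16.8%,
$\sigma_{add}$ 1.76 mg/L. The covariate equations are normalized at
$WT_{ref} = 1$ kg and $SCr_{ref} = 42$ µmol/L (the cohort median); both
references are configuration, not code, so alternative normalizations are
a config change.

Concentrations are computed from the analytic biexponential solution,
superposed over the dose history; a finite infusion is represented as an
infinite infusion minus the same infusion delayed by its duration. The
degenerate equal-hybrid-root case switches to the analytic limit at a
relative root gap of $10^{-10}$, and $Q = 0$ reduces exactly to the
one-compartment equation. The tests verify the solution against adaptive
ODE integration to a relative error below $10^{-6}$.

## Preprocessing rules

Event records follow NONMEM-like semantics (one row per dose or
observation; column dictionary in `?parse_dataset`). The cleaning rules
mirror EHR-derived practice for this population:

* observations more than 7 days after the start of the last infusion are
  removed; samples drawn strictly during an infusion are removed (a
  sample exactly at the end of the infusion is a peak and is kept);
* subjects started on vancomycin before 7 days of postnatal age are
  excluded (maternal creatinine confounds renal-function estimation);
* serum creatinine below its 15 µmol/L quantification limit is set to
  7.5 µmol/L; vancomycin concentrations below 1 mg/L are flagged BLQ and
  retained as censored records;
* creatinine is imputed nearest-in-time (equidistant ties take the
  earlier value — conservative toward the pre-dose renal state), weight
  by linear interpolation with linear end-segment extrapolation.

Dosing occasions are separated by inter-dose gaps above 7 days (inclusive
threshold; configurable). The episode-combination rule of the source data
set is not documented there, so this gap rule is a stated stand-in that
mirrors the 7-day observation window.

## Estimation

Individual estimation is MAP: the mode of
$-2\log p(\eta \mid y) = \sum_{obs}\left[\left(\frac{y-f}{sd}\right)^2 +
2\log sd\right] - 2\sum_{BLQ}\log\Phi\!\left(\frac{LLOQ - f}{sd}\right) +
\eta'\Omega^{-1}\eta$, with the residual SD evaluated at the individual
prediction (interaction) and BLQ records entering through the M3 censored
likelihood. Because the random effects act on clearance alone, the
single-occasion posterior depends on the data only through
$u = \eta^{BSV}+\eta^{BOV}$; the implementation exploits this to reduce
the inner problem to an exact one-dimensional search (Brent), with the
two-dimensional posterior Hessian recovered analytically from the 1-D
data curvature. Multi-occasion subjects use bounded quasi-Newton with
deterministic jittered restarts. Posterior draws use the Laplace
(multivariate normal) approximation.

One consequence of the interaction term worth knowing: even when the data
equal the zero-eta prediction exactly, the $2\log sd$ term pulls the mode
slightly negative (order 0.01 here). The tests pin the exact stationarity
property in the additive-error limit.

Population fitting maximizes the Laplace-approximated marginal
likelihood: per subject, the conditional mode plus the log-determinant
correction, which for this model class coincides with conditional-mode
(FOCE-type, with interaction) estimation to within optimizer tolerance
and extends cleanly to the M3 terms. Constant $2\pi$ data terms are
dropped; they affect neither estimates, standard errors, nor objective
differences between nested models. Fixed effects and variance components
are estimated on the log scale; confidence intervals are
$\hat\theta\,e^{\pm 1.645\,SE}$. The condition number is the eigenvalue
ratio of the correlation matrix of the estimates (reference limit 1000).
Shrinkage is $1 - SD(EBE)/\omega$, reported per effect and pooled,
because the source does not state whether its overall figure pools BSV
and BOV. The variance-explained metric is a documented reconstruction
(the source defines none): the across-subject variance of log typical
clearance with a covariate subset active, divided by the all-covariate
variance plus $\omega^2_{BSV}+\omega^2_{BOV}$.

## Dose individualization

The target is a steady-state AUC$_{24}$/MIC of 400–600 h (MIC 1 mg/L by
default). For linear kinetics AUC$_{24}$ = daily dose / $CL$, so with
clearance-only random effects every individual AUC distribution is
log-normal and the probability of target attainment (PTA) has a closed
form; a Monte-Carlo path (default 4000 samples, common random numbers
across the grid) is kept for generality and is cross-checked against the
closed form in the tests. PTA is computed on the exposure itself —
residual assay error is excluded deliberately, since the target is AUC,
not a measurement of it.

Optimization is exhaustive over a dose × interval grid (default 5–30
mg/kg in 0.5 mg/kg steps; intervals 6–48 h; 1-h infusions). PTA ties
within $10^{-3}$ break toward the lowest total daily dose, then the
longest interval, minimizing nephrotoxic exposure; note this implies that
under a near-point-mass clearance the selected dose sits at the *bottom*
of the target window, not its middle.

Four approaches are implemented: weight-based initial dosing (mg/kg),
model-based empirical optimization under the population prior,
steady-state trough targeting (dose scaled linearly to an 8.5 mg/L
trough, the midpoint of the previously recommended 7–10 mg/L window), and
model-based Bayesian optimization from the MAP posterior.

Two genuinely open choices were resolved as follows:

* **Forecast horizon.** Maintenance-dose adjustment applies to the
  *ongoing* course, so by default the posterior carries both the
  between-subject and the current occasion's effect forward
  (`cl_posterior(..., horizon = "current_occasion")`). For planning a
  later, separate course, `"new_occasion"` regenerates the occasion
  effect from its prior and carries only the between-subject effect.
  The distinction matters: with one trough and one peak, the attainable
  PTA ceiling is ≈ 0.90 within the course but only ≈ 0.74–0.79 across
  courses, where the fresh occasion variability is irreducible.
* **Attained-PTA evaluation.** `evaluate_approaches()` scores every
  approach under each subject's MAP-posterior AUC distribution — the only
  evaluation possible with real data, where no simulation truth exists —
  and exposes `eval_dist = "truth"` (true between-subject effect plus
  between-occasion prior) for simulation studies.

## The synthetic cohort

`generate_cohort()` emulates the demographic structure of the study
population from its published marginal summaries: gestational age
truncated-normal (median 30.1, IQR 6.9, range 24.1–41.3 weeks); postnatal
age at first dose, birth weight, serum creatinine and per-kg dose
truncated log-normal, moment-matched to median and IQR (for a log-normal,
$\sigma = \operatorname{asinh}(IQR/2m)/z_{0.75}$). Gestational age and
birth weight share a Gaussian copula with correlation 0.7 — an
assumption; the true joint structure is unreported. Weight grows linearly
at 1.5% of birth weight per day, which reproduces the reported median
body weight at first dose (1.68 kg). Courses are 8 doses of ~14 mg/kg,
with the interval assigned by PMA at first dose (< 30 wk q12h, 30–37 wk
q8h, ≥ 37 wk q6h), matching common neonatal practice within the q6–q12 h
range observed. The default sampling design is one trough immediately
before and one peak at the end of the infusion of dose 4, the guideline's
"one trough, preferably plus one peak". True random effects are drawn
from the model's BSV/BOV distributions and recorded, and
`simulate_observations()` adds combined-error noise with censoring below
1 mg/L.

What the generator does *not* emulate: SCr–PMA and SCr–renal-function
correlations, within-subject creatinine drift, irregular real-world
sampling times, site or sex composition effects, and any interval
assignment driven by renal function rather than PMA. Passing tests on
this cohort therefore demonstrate internal consistency of the method
under the model, not agreement with any real data set.

## What the checks do and do not show

Two results of the source analysis are data-bound and cannot be
recomputed without the original EHR cohort (its OFV, condition number,
shrinkage and exact estimates); the package instead verifies what is
analytically checkable (the LRT p-value of 0.06 for freeing the
allometric exponents at 2 df; 50% maturation at $Mat_{50}$) and
reproduces the *behavioral* findings on the calibrated synthetic cohort:

* Bayesian optimization holds a per-subject PTA floor above 75% (50
  subjects, one trough + one peak each).
* Parameter recovery: fitting 100 subjects with 4 samples each (three
  troughs, one peak; volumes and variance components fixed at their
  generating values — a deliberate scaled-down design) recovers TVCL,
  $H$, $Mat_{50}$ and $\theta_{SCr}$. A single such fit estimates log
  TVCL with a sampling SD of ~8% (TVCL rides a likelihood ridge with the
  maturation parameters), so the recovery check pools ten replicate
  fits; its measured bias is about −4%.
* The trough-based comparator *underperforms more strongly here than in
  the source report* (cohort-median PTA of a few percent rather than
  ≈ 50%): under these parameters an 8.5 mg/L steady-state trough at
  q6–q12 h dosing corresponds to AUC$_{24}$ ≈ 250–430 mg·h/L — mostly
  below the 400 target floor. The AUC/trough ratio rises with the dosing
  interval (≈ 30–50 h at q6–q12, ≈ 60–80 h at q18–q24), so the source
  cohort's real-world interval mix plausibly explains its milder figure;
  the synthetic generator is fixed to q6–q12 h regimens. This
  discrepancy is reported as-is rather than recalibrated.
* Self-consistency of diagnostics: on model-simulated data ~95% of pcVPC
  bin percentiles fall inside their simulated confidence intervals, and
  ~5% of conditional weighted residuals exceed |1.96|.

## Numerical choices

Inner (MAP) optimization: Brent on $[-5, 5]$ at $10^{-8}$ tolerance for
single-occasion subjects, otherwise BFGS (relative tolerance $10^{-10}$,
bounded at $|\eta| \le 10$ with a smooth pull-back). Outer (population)
optimization: BFGS on log parameters, relative tolerance $10^{-6}$,
warm-started conditional modes. Steady state: dose superposition until
the accumulation tail is below $10^{-10}$ relative. pcVPC: quantile
binning on time after dose (default 8 bins), bins under 3 observations
merged leftward and counted; BLQ observations are excluded from
percentile statistics and drive the censored-fraction panel. All
stochastic functions take explicit seeds and restore the caller's RNG
state.

## Known limitations

Laplace/MAP machinery assumes a unimodal, approximately Gaussian
conditional posterior; with one or two observations and strong censoring
this is an approximation (the grid-search oracles in the tests bound its
error on small cases). Covariates are evaluated at each occasion's first
dose and held constant within the occasion, which is adequate for
few-day courses but not for rapidly changing renal function within a
course. No saturable elimination, no covariates beyond weight, PMA and
creatinine, and no MIC-distribution (CFR) analysis are provided.
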