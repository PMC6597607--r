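---
title: "Models and methods in pedpk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in pedpk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(pedpk)
```

`pedpk` fits hierarchical nonlinear mixed-effects (NLME) models to
pediatric pharmacokinetic studies and uses the resulting allometric
covariate function to scale adult clearance of CYP3A substrates to
children. This vignette documents the models, the numerical methods, and
the design decisions behind them, in enough detail that a reader can
judge what the package's tests do and do not demonstrate.

## Structural and stochastic model

All parameters are *apparent* (CL/F scale): the studies the package
emulates are oral-only, so bioavailability is not identifiable and is
absorbed into clearance and volume. Units are fixed throughout — hours,
mg, kg, L, L/h, concentrations in mg/L — to remove any ambiguity.

Two structural models are provided, both with first-order absorption
from a depot at a fixed rate constant `ka` (absorption is not estimable
in either emulated design; the dense-design default is 3.5 1/h, giving a
t_max near 0.5 h, and the sparse steady-state default is 1 1/h):

* a **two-compartment single-dose oral** model, solved analytically via
  its macro-constant tri-exponential form. Coincident exponential rates
  (`ka` equal to a disposition rate, or the two disposition rates equal)
  are separated by a 1e-8 relative perturbation so the closed form never
  divides by zero. The analytical solution is verified in the test suite
  against a numerical linear-ODE oracle (deSolve) at relative tolerance
  1e-6 over a 100-point grid, and against the one-compartment solution in
  the nested limit (intercompartmental clearance and peripheral volume
  going to zero).
* a **one-compartment steady-state oral** model for repeated dosing
  every `tau` hours, in its closed superposition form, verified against a
  truncated 200-dose superposition sum and periodic by construction
  (trough value at 0 equals the value at `tau`). The dosing interval of
  the sparse design is not fixed by the emulated study's published
  sampling scheme beyond "trough and up to 8 h post-dose"; the package
  default is `tau = 8` h, configurable.

Inter-individual variability is log-normal: an individual parameter is
`P_i = theta_TV * prod((COV_i / COV_med)^theta_COV) * exp(eta_i)` with
`eta_i ~ N(0, omega^2)` on a diagonal covariance (off-diagonal Omega is
out of scope). Continuous covariates (body weight, age) enter as power
terms referenced at the study median; sex enters as an estimated
female-to-male fraction on the typical value. Residual error is
`Y = C_pred (1 + eps1) + eps2` with `eps1 ~ N(0, sigma2_prop)` and an
optional additive `eps2 ~ N(0, sigma2_add)`. The dense-design reference
parameterization carries IIV on clearance and central volume only, and a
proportional-only residual — the parsimonious choice consistent with a
parameter table that reports exactly those terms; the additive component
remains available through `errorModel = "combined"`.

## Marginal likelihood

The estimation target is the Laplace approximation *with interaction*:
for each subject, the joint -2 log density of (observations, eta) is
minimized over eta, and the marginal -2 log-likelihood is the Laplace
expansion at that conditional mode with the residual variance
`sigma2_prop * f(eta)^2 + sigma2_add` evaluated at the individual
prediction. Evaluated at the conditional mode, this is the FOCE-I
objective family, and the package accepts `"focei"` and `"laplace"` as
synonyms for it. The full 2*pi constants are included so that the
objective is directly comparable with adaptive Gauss-Hermite quadrature;
the test suite holds the objective to within 0.1 OFV units of a 21-node
adaptive quadrature oracle on the shipped three-subject fixtures
(and the oracle itself is validated against direct numerical
integration).

Three numerical decisions matter here:

* **Inner optimization.** The conditional density can be multimodal —
  with a large volume-of-distribution variance (the dense-design
  reference has omega^2 = 1.19 on Vc) and proportional error, sparse or
  noisy subjects can have two competing eta solutions. Newton iteration
  therefore starts from eta = 0 *and* from plus/minus one prior standard
  deviation along each axis, keeping the deepest mode (gradient
  tolerance 1e-8, all starts deterministic).
* **Curvature floor.** At weakly identified conditional modes the exact
  Hessian can lose definiteness or collapse along a flat direction,
  which would let the Laplace determinant term diverge and reward
  degeneracy. The curvature used for Newton steps and for the Laplace
  determinant is the exact (finite-difference) Hessian with its spectrum
  floored, in the metric of the expected (Gauss-Newton) information of
  the conditional normal model, at 10% — a transformation that is
  continuous in the parameters, always positive definite, and exactly
  the Hessian wherever the data are informative (on the shipped
  fixtures the floor never engages).
* **Outer optimization.** Typical values, sex fractions and variances
  are optimized on the log scale (positivity by construction);
  covariate exponents untransformed (their sign is data-determined).
  Because conditional modes can shift discretely as the population
  parameters move, the objective carries small kinks that can stall a
  pure quasi-Newton method; the outer optimizer therefore alternates
  `nlminb` passes with Nelder-Mead refinements until the OFV is stable,
  declaring convergence at a fixed point (cycle improvement below 0.01
  OFV units). Refitting from a returned optimum changes the OFV by at
  most 0.01 — a property the test suite asserts.

Relative standard errors come from a central finite-difference Hessian
of the objective at the optimum, with *moderate* relative steps (5%):
tiny steps would amplify the conditional-mode kinks, while at 5% the
quadratic signal dominates them. The sampling covariance is
`2 * H^-1` since the objective is -2 log L. RSEs are diagnostics; the
package reports `NA` where the Hessian is not usable rather than
guessing.

Empirical Bayes estimates are the per-subject conditional modes (the
same inner optimization); a subject without observations sits at the
prior mode eta = 0, and eta shrinks to 0 with omega^2. CWRES are the
FOCE-linearized residuals: the model is linearized in eta at the
empirical Bayes estimate, and the population-corrected residual
`y - (f - G eta_hat)` is decorrelated with the Cholesky factor of
`G Omega G' + diag(sigma2_prop f^2 + sigma2_add)`. Under the generating
model the test suite requires their mean in (-0.1, 0.1) and SD in
(0.85, 1.15) on a 200-subject simulated study; the linearization leaves
a small negative bias visible at smaller study sizes, which is expected
of this diagnostic rather than a defect of the fit.

## Covariate selection

`stepwiseCovariates()` performs forward inclusion then backward
deletion. A candidate (weight or age as a power term referenced at the
study median; sex as a fraction) is eligible in a forward step when its
OFV drop reaches the chi-square threshold `qchisq(0.99, 1) = 6.63`
(p < 0.01) *and* the relevant variance component — the parameter's IIV
if it has one, otherwise the residual variance — decreased; the largest
eligible drop wins, with exact ties resolved by the deterministic
(weight, age, sex) x (cl, vc/v, vp, q) order. Backward deletion removes
included covariates one at a time, smallest OFV rise first, while the
rise does not exceed `qchisq(0.995, 1) = 7.88` (p < 0.005); deletion is
sequential single-removal until no removal passes, which is the
conservative reading where the alternative (joint re-testing) is
underdetermined. Weight and age are both offered on all parameters; a
collinearity note is logged when their correlation exceeds 0.9, which in
pediatric data is the rule rather than the exception — selection
between them is then weakly determined and the decision log should be
read with that in mind.

## Bootstrap and NPDE

The bootstrap resamples subjects with replacement (study size
preserved), refits from the original estimates (a speed choice that is
standard practice), and summarizes converged replicates by the median
and the 5th/95th percentiles. The percentile convention is linear
interpolation between order statistics (`quantile` type 7), fixed and
documented because conventions differ; more than 20% non-convergence
flags the result without discarding it. Resampling is unstratified —
stratifying by weight would be a defensible alternative, but nothing in
the emulated analyses requires it.

NPDE simulates `nSim` replicate observation vectors per subject,
decorrelates observed and simulated vectors with the empirical mean and
Cholesky factor of the simulated covariance, ranks each observation
among its simulations with a half-count continuity correction
`pd = (#{sim < obs} + 0.5) / (nSim + 1)`, randomizes ranks within ties,
and maps through the standard-normal quantile. Each subject's
simulation stream is keyed to the subject's identity (not its position),
so results are invariant to subject order and reproducible per seed. A
zero-variance simulated component is an error (degenerate model); a
merely ill-conditioned covariance gets a 1e-8 diagonal ridge, logged.
Under the generating model, the npde pass a N(0,1) Kolmogorov-Smirnov
check at alpha = 0.01 in at least 18 of 20 seeds with `nSim = 200` — the
scaled-down simulation count used by the tests; the package default is
1000.

## Synthetic study designs

The two generators emulate the designs behind the reference
parameterizations; they define study conditions, not tunable test
fixtures.

* **Dense design** (midazolam-like): 31 subjects; weights log-uniform on
  9.5-83.2 kg (the published range; only median and range are known, and
  log-uniform respects the right skew of pediatric weights); a single
  oral dose of about 0.45 mg/kg rounded to 0.5 mg and clamped to
  3-15 mg, matching the published median of 12.5 mg at the median
  weight; 8-11 of the 11 nominal times 0.25-22 h retained per subject
  (median 10); each nominal time jittered by +/-10% because sampling in
  practice happens "around" nominal times and the estimator should not
  depend on exact grids.
* **Sparse design** (sildenafil-like): 156 subjects; weights log-uniform
  on 8.2-106 kg; low/medium/high dose groups of 39/48/69 with
  weight-stratified doses (medium 10/20/40 mg and high 20/40/80 mg for
  up to 20 / 20-45 / over 45 kg; low 10 mg only above 20 kg — lighter
  subjects assigned to low are swapped with a heavier medium/high
  subject, preserving group sizes); 1-4 steady-state samples per subject
  (median 4) at trough and around 3, 6 and 8 h post-dose.

Age is derived from weight by a monotone map (`(WT - 8)/2.8` years,
log-normal jitter, clamped to 1-17 y) chosen to land near the published
median ages; the real joint weight-age-dose distributions are not
public, so only the marginals are matched. This is a synthetic
convention, and analyses that depend on the weight-age joint (notably
weight-versus-age covariate selection) inherit it.

One consequence of the error model deserves emphasis: with the sparse
design's large proportional variance (0.627), the Gaussian residual
model generates a nontrivial fraction of negative concentrations. The
generator *keeps* them when the error model is proportional-only,
because truncating would bias simulation-re-estimation — the estimator
assumes exactly the generating density. When an additive component is
enabled, negative values are truncated at zero and counted in the truth
record, reflecting that assays do not report negative concentrations.
Real datasets, of course, contain no negative values; this is a place
where the synthetic data are deliberately more faithful to the model
than to an assay.

What passing tests show: the estimator recovers the generating typical
clearance within 15% and the weight exponent within 0.15 (medians over
five seeds) under both designs, the likelihood agrees with quadrature,
and the diagnostics are calibrated *under the model*. What they do not
show: robustness to model misspecification (absorption delays,
nonlinear elimination, assay censoring), which no simulation from the
fitted model class can demonstrate.

## Extrapolation criteria

`minAccurateAge()` encodes the drug-property criteria for accurate
neonatal (1-day) scaling. For HSA-bound substrates the admissible adult
extraction-ratio window runs from 0.05-0.55 at high protein binding
(f_u <= 0.1) to 0.35-0.65 at low binding (f_u >= 0.9); the underlying
framework states the bounds change gradually between these anchors
without giving the function, so the package interpolates linearly in
f_u and clamps outside — the minimal assumption, documented as such.
For AAG-bound substrates no scenario is accurate at f_u >= 0.4; the
window runs from 0.1-0.5 at f_u <= 0.025 (binding of at least 97.5%,
treated as a clamped anchor) to 0.4-0.6 at f_u near 0.1, interpolating
linearly between; for f_u between 0.1 and 0.4 no criterion is stated and
the verdict is indeterminate. Scaling assumes CYP3A mediates at least
75% of metabolism; below that the verdict is indeterminate with a
warning. Finer age classes (1 month through 5 years) are not derivable
from the stated criteria; they come from an optional user-supplied
lookup grid, and a per-drug reference table of minimum-age classes ships
in `inst/extdata/` for reporting. Prediction errors in reports are
rounded to one decimal; classification uses the unrounded value.

The extrapolation function itself deliberately stops at 1 year: the
dense-design study contains no children younger than that, and CYP3A
maturation below 1 year would make extrapolation an overprediction.

## Problem sizes

The test suite and the acceptance script use: five
simulation-re-estimation seeds per design (31 and 156 subjects); 20
calibration seeds with 200 NPDE simulations; 50 bootstrap resamples on a
40-subject design for coverage checks; and the three-subject fixtures
for quadrature comparisons. These sizes were chosen to give each check
statistical teeth while keeping a full run in minutes on a single CPU;
package defaults (bootstrap 250, NPDE 1000) follow the conventional
analysis sizes instead.

## Known limitations

* Diagonal Omega only; no interoccasion variability; no SAEM or
  importance-sampling estimators.
* One- and two-compartment oral models only; no IV administration,
  lag or transit absorption, metabolites, or nonlinear elimination.
* The steady-state solution assumes strict dose-interval periodicity.
* CWRES carry the usual FOCE linearization bias, visible as a slightly
  negative mean in small studies.
* The extrapolation criteria are bright-line windows derived from a
  physiological framework; drugs near a window edge deserve the full
  framework rather than this package's lookup.
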