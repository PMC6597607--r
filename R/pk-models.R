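## Structural PK models: analytical solutions for first-order oral
## absorption, in apparent (CL/F) parameters. Coincident exponential rates
## (ka equal to a disposition rate, or alpha equal to beta) are separated by
## a 1e-8 relative perturbation inside the compiled kernels, so the
## macro-constant forms never return NaN.

#' Two-compartment oral model, single dose
#'
#' Tri-exponential concentration after a single oral dose at t = 0, with
#' first-order absorption into a central compartment exchanging with one
#' peripheral compartment. When `q` or `vp` is zero the model collapses to
#' the one-compartment solution.
#'
#' @param dose dose amount (mg).
#' @param t time(s) since the dose (h); vectorized.
#' @param cl apparent clearance CL/F (L/h).
#' @param vc apparent central volume Vc/F (L).
#' @param q apparent intercompartmental clearance Q/F (L/h).
#' @param vp apparent peripheral volume Vp/F (L).
#' @param ka first-order absorption rate constant (1/h).
#' @return concentrations (mg/L), zero at t <= 0.
#' @examples
#' conc2cmtOral(12.5, c(0.5, 2, 8), cl = 102.6, vc = 156, q = 121.8,
#'              vp = 255, ka = 3.5)
#' @export
conc2cmtOral <- function(dose, t, cl, vc, q, vp, ka) {
  stopifnot(dose > 0, cl > 0, vc > 0, q >= 0, vp >= 0, ka > 0,
            all(is.finite(t)))
  cpp_conc2cmt(dose, as.numeric(t), cl, vc, q, vp, ka)
}

#' One-compartment oral model, single dose
#'
#' @inheritParams conc2cmtOral
#' @param v apparent volume of distribution V/F (L).
#' @return concentrations (mg/L).
#' @export
conc1cmtOral <- function(dose, t, cl, v, ka) {
  stopifnot(dose > 0, cl > 0, v > 0, ka > 0, all(is.finite(t)))
  cpp_conc1cmt(dose, as.numeric(t), cl, v, ka)
}

#' One-compartment oral model at steady state
#'
#' Superposition solution for repeated dosing every `tau` hours at
#' equilibrium; periodic, so the value at `tAfterDose = 0` (trough, just
#' before a dose) equals the value at `tAfterDose = tau`.
#'
#' @inheritParams conc1cmtOral
#' @param tau dosing interval (h).
#' @param tAfterDose time(s) after the last dose, in `[0, tau]`; vectorized.
#' @return steady-state concentrations (mg/L).
#' @export
conc1cmtOralSS <- function(dose, tau, tAfterDose, cl, v, ka) {
  stopifnot(dose > 0, tau > 0, cl > 0, v > 0, ka > 0)
  t <- as.numeric(tAfterDose)
  if (any(t < 0 | t > tau))
    stop("tAfterDose must lie within [0, tau]")
  cpp_conc1cmt_ss(dose, tau, t, cl, v, ka)
}

#' Individual parameter value under covariate and random effects
#'
#' Computes `tv * prod((COV_i / COV_ref)^exponent) * sexFraction^[female]
#' * exp(eta)`: the log-normal inter-individual model with power covariate
#' terms on a typical value.
#'
#' @param tv typical parameter value (> 0).
#' @param covTerms list of terms from [covTerm()] (may be empty).
#' @param subject a list (or one-row data.frame) with the covariates the
#'   terms require: `weight` (kg), `age` (years), `sex` (0 male / 1 female).
#' @param eta the subject's random effect on the log scale (default 0).
#' @param sexFraction optional female-to-male fraction applied when
#'   `subject$sex == 1`.
#' @return the individual parameter value (strictly positive).
#' @examples
#' wt <- covTerm("cl", "weight", reference = 70, fixed = 0.874)
#' individualParam(100, list(wt), list(weight = 28), eta = 0)  # 44.9 L/h
#' @export
individualParam <- function(tv, covTerms = list(), subject, eta = 0,
                            sexFraction = NULL) {
  stopifnot(tv > 0)
  val <- tv
  for (ct in covTerms) {
    cov <- subject[[ct$covariate]]
    if (is.null(cov) || is.na(cov))
      stop("subject is missing covariate '", ct$covariate, "'")
    expo <- if (is.null(ct$fixed)) ct$exponent else ct$fixed
    if (is.null(expo)) expo <- ct$exponent
    if (is.null(expo))
      stop("covariate term on '", ct$parameter,
           "' has no exponent value; supply 'fixed' or an 'exponent'")
    val <- val * (cov / ct$reference)^expo
  }
  if (!is.null(sexFraction) && !is.null(subject$sex) &&
      isTRUE(subject$sex == 1))
    val <- val * sexFraction
  val * exp(eta)
}

#' Residual error mapping
#'
#' Combined proportional and additive residual model
#' `Y = Cpred * (1 + eps1) + eps2`.
#'
#' @param cPred model-predicted concentration(s), >= 0.
#' @param eps1 proportional error realization(s).
#' @param eps2 additive error realization(s).
#' @return the observed-scale concentration(s).
#' @export
residualMap <- function(cPred, eps1 = 0, eps2 = 0) {
  stopifnot(all(cPred >= 0))
  cPred * (1 + eps1) + eps2
}
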