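## S4 classes for the popPK pipeline. All parameters are apparent (CL/F
## scale) since only oral data are modelled; units are fixed throughout:
## time h, dose mg, weight kg, volume L, clearance L/h, concentration mg/L.

REQUIRED_COLUMNS <- c("ID", "TIME", "AMT", "EVID", "SS", "II", "DV", "MDV",
                      "WT", "AGE", "SEX")

#' PKStudy: a longitudinal pharmacokinetic study
#'
#' A set of subjects with covariates (body weight in kg, age in years, sex),
#' dosing records and timed concentration observations, stored as a
#' NONMEM-style long table. Dose rows have `EVID = 1` (with `SS = 1` and a
#' dosing interval `II` for steady-state dosing); observation rows have
#' `EVID = 0` and the measured concentration in `DV` (mg/L). `SEX` is coded
#' 0 = male, 1 = female.
#'
#' For steady-state designs, `TIME` on observation rows is the time after
#' the last dose within the dosing interval (0 to `II`).
#'
#' @slot data a `data.frame` with columns ID, TIME, AMT, EVID, SS, II, DV,
#'   MDV, WT, AGE, SEX.
#' @slot truth a list carrying the generating parameters for simulated
#'   studies (empty for real data).
#' @export
setClass("PKStudy", representation(data = "data.frame", truth = "list"))

setValidity("PKStudy", function(object) {
  d <- object@data
  miss <- setdiff(REQUIRED_COLUMNS, names(d))
  if (length(miss) > 0)
    return(paste("missing columns:", paste(miss, collapse = ", ")))
  if (nrow(d) == 0) return("study contains no rows")
  if (any(!is.finite(d$TIME))) return("non-finite TIME")
  if (any(d$TIME < 0)) return("negative observation/dose times")
  if (any(d$WT <= 0)) return("body weight must be > 0")
  if (any(d$AGE < 0)) return("age must be >= 0")
  if (!all(d$EVID %in% c(0, 1))) return("EVID must be 0 or 1")
  if (!all(d$SEX %in% c(0, 1))) return("SEX must be coded 0 (male) / 1 (female)")
  dose <- d[d$EVID == 1, , drop = FALSE]
  if (any(dose$AMT <= 0)) return("dose amounts must be > 0")
  if (any(dose$SS == 1 & dose$II <= 0))
    return("steady-state doses require a positive dosing interval II")
  TRUE
})

#' ModelSpec: structural and stochastic model specification
#'
#' @slot compartments 1 or 2 (disposition compartments; absorption is always
#'   first order from a depot).
#' @slot ka fixed first-order absorption rate constant (1/h).
#' @slot dosing `"single"` (one oral dose at t = 0) or `"steady_state"`
#'   (multiple-dose equilibrium with interval II).
#' @slot iiv character vector of structural parameter names carrying
#'   log-normal inter-individual variability (subset of `cl`, `vc`, `q`,
#'   `vp` for 2-compartment; `cl`, `v` for 1-compartment).
#' @slot errorModel `"proportional"` or `"combined"` residual error.
#' @slot covariates list of covariate terms; each a list with elements
#'   `parameter`, `covariate` (`"weight"` or `"age"`), `reference`
#'   (covariate units), and either `theta` (name of the estimated exponent)
#'   or `fixed` (a fixed exponent value).
#' @slot sexTerms list of sex terms; each a list with `parameter` and
#'   `theta`, the name of the female-to-male fraction.
#' @export
setClass("ModelSpec", representation(
  compartments = "numeric", ka = "numeric", dosing = "character",
  iiv = "character", errorModel = "character",
  covariates = "list", sexTerms = "list"))

setValidity("ModelSpec", function(object) {
  if (!object@compartments %in% c(1, 2)) return("compartments must be 1 or 2")
  if (object@ka <= 0) return("ka must be > 0")
  if (!object@dosing %in% c("single", "steady_state"))
    return("dosing must be 'single' or 'steady_state'")
  if (object@compartments == 2 && object@dosing == "steady_state")
    return("steady-state dosing is only implemented for the 1-compartment model")
  if (!object@errorModel %in% c("proportional", "combined"))
    return("errorModel must be 'proportional' or 'combined'")
  pnames <- structuralNames(object)
  if (!all(object@iiv %in% pnames))
    return("iiv names must be structural parameters of the model")
  for (ct in object@covariates) {
    if (!all(c("parameter", "covariate", "reference") %in% names(ct)))
      return("covariate terms need parameter, covariate, reference")
    if (!ct$parameter %in% pnames) return("covariate on unknown parameter")
    if (!ct$covariate %in% c("weight", "age"))
      return("covariate must be 'weight' or 'age'")
    if (ct$reference <= 0) return("covariate reference must be > 0")
    if (is.null(ct$theta) && is.null(ct$fixed))
      return("covariate term needs either a theta name or a fixed exponent")
  }
  for (st in object@sexTerms) {
    if (!all(c("parameter", "theta") %in% names(st)))
      return("sex terms need parameter and theta")
    if (!st$parameter %in% pnames) return("sex term on unknown parameter")
  }
  TRUE
})

#' ParameterSet: the estimable state of a population PK model
#'
#' @slot thetas named positive reals: typical values of structural
#'   parameters (named as the parameter, e.g. `cl`) plus covariate exponents
#'   and sex fractions (named as referenced by the [ModelSpec]).
#' @slot omega2 named non-negative reals: diagonal variances of the
#'   log-normal inter-individual random effects.
#' @slot sigma2prop variance of the proportional residual error.
#' @slot sigma2add variance of the additive residual error (0 when absent).
#' @slot fixed character vector naming entries that are not estimated
#'   (theta names, `omega2.<name>`, `sigma2prop`, `sigma2add`).
#' @export
setClass("ParameterSet", representation(
  thetas = "numeric", omega2 = "numeric",
  sigma2prop = "numeric", sigma2add = "numeric", fixed = "character"))

setValidity("ParameterSet", function(object) {
  if (is.null(names(object@thetas)) && length(object@thetas) > 0)
    return("thetas must be named")
  if (length(object@omega2) > 0 && is.null(names(object@omega2)))
    return("omega2 must be named")
  if (any(object@omega2 < 0)) return("omega2 variances must be >= 0")
  if (object@sigma2prop < 0 || object@sigma2add < 0)
    return("residual variances must be >= 0")
  TRUE
})

#' FitResult: the outcome of a maximum-likelihood fit
#'
#' @slot estimates the estimated [ParameterSet].
#' @slot ofv objective function value, -2 x approximate log marginal
#'   likelihood (including 2*pi constants).
#' @slot rse named relative standard errors (percent) of the estimates.
#' @slot etas matrix of empirical Bayes random-effect estimates, one row per
#'   subject (columns follow the model's `iiv`).
#' @slot converged logical.
#' @slot nEvals number of objective evaluations used by the outer optimizer.
#' @slot model the fitted [ModelSpec].
#' @export
setClass("FitResult", representation(
  estimates = "ParameterSet", ofv = "numeric", rse = "numeric",
  etas = "matrix", converged = "logical", nEvals = "integer",
  model = "ModelSpec"))

setValidity("FitResult", function(object) {
  if (isTRUE(object@converged) && !is.finite(object@ofv))
    return("converged fit must have a finite OFV")
  TRUE
})

#' ScalingFunction: allometric clearance scaling from a reference subject
#'
#' Encodes CL(WT) = clRef * (WT / wtRef)^exponent. The package default
#' (70 kg reference, exponent 0.874) is the pediatric covariate function for
#' CYP3A-mediated midazolam clearance used for between-drug extrapolation.
#'
#' @slot clRef reference clearance (L/h), apparent or systemic at the
#'   caller's consistency.
#' @slot wtRef reference body weight (kg).
#' @slot exponent allometric exponent (dimensionless).
#' @export
setClass("ScalingFunction", representation(
  clRef = "numeric", wtRef = "numeric", exponent = "numeric"))

setValidity("ScalingFunction", function(object) {
  if (object@clRef <= 0) return("clRef must be > 0")
  if (object@wtRef <= 0) return("wtRef must be > 0")
  TRUE
})

#' BootstrapResult: nonparametric bootstrap summary of a fit
#'
#' @slot median named per-parameter bootstrap medians.
#' @slot ciLower,ciUpper named 5th / 95th percentiles (the 90% CI).
#' @slot nResamples,nConverged resample counts.
#' @slot flagged TRUE when more than 20% of resamples failed to converge.
#' @slot samples matrix of per-resample estimates (converged rows only).
#' @export
setClass("BootstrapResult", representation(
  median = "numeric", ciLower = "numeric", ciUpper = "numeric",
  nResamples = "integer", nConverged = "integer", flagged = "logical",
  samples = "matrix"))

setValidity("BootstrapResult", function(object) {
  if (object@nConverged > object@nResamples)
    return("nConverged cannot exceed nResamples")
  if (any(object@ciLower > object@median + 1e-12) ||
      any(object@median > object@ciUpper + 1e-12))
    return("CI must bracket the median")
  TRUE
})

#' NpdeResult: normalized prediction distribution errors
#'
#' @slot values per-observation npde values (approximately N(0,1) under a
#'   correct model), in study row order of the non-missing observations.
#' @slot tests data.frame of the mean-zero, unit-variance, normality and
#'   global (Bonferroni) tests.
#' @slot nSim number of simulated replicates used.
#' @export
setClass("NpdeResult", representation(
  values = "numeric", tests = "data.frame", nSim = "integer"))

#' DrugProperties: adult drug properties governing extrapolation accuracy
#'
#' @slot name drug name.
#' @slot extractionRatio adult hepatic extraction ratio, in (0, 1).
#' @slot fu unbound fraction in adult plasma, in (0, 1].
#' @slot bindingProtein `"HSA"` (albumin) or `"AAG"` (alpha-1-acid
#'   glycoprotein).
#' @slot fCyp3a fraction of total metabolism mediated by CYP3A.
#' @export
setClass("DrugProperties", representation(
  name = "character", extractionRatio = "numeric", fu = "numeric",
  bindingProtein = "character", fCyp3a = "numeric"))

setValidity("DrugProperties", function(object) {
  if (object@extractionRatio <= 0 || object@extractionRatio >= 1)
    return("extractionRatio must lie in (0, 1)")
  if (object@fu <= 0 || object@fu > 1) return("fu must lie in (0, 1]")
  if (!object@bindingProtein %in% c("HSA", "AAG"))
    return("bindingProtein must be 'HSA' or 'AAG'")
  if (object@fCyp3a < 0 || object@fCyp3a > 1)
    return("fCyp3a must lie in [0, 1]")
  TRUE
})

#' AccuracyVerdict: minimum age of accurate clearance scaling
#'
#' @slot minAgeClass one of `"1 day"`, `"1 month"`, `"6 months"`,
#'   `"1 year"`, `"2 years"`, `"5 years"`, `"not_accurate_le_5y"`,
#'   `"indeterminate"`.
#' @slot basis `"text_criteria"` or `"lookup_table"`.
#' @export
setClass("AccuracyVerdict", representation(
  minAgeClass = "character", basis = "character"))

AGE_CLASSES <- c("1 day", "1 month", "6 months", "1 year", "2 years",
                 "5 years", "not_accurate_le_5y", "indeterminate")

setValidity("AccuracyVerdict", function(object) {
  if (!object@minAgeClass %in% AGE_CLASSES)
    return("unknown age class")
  if (!object@basis %in% c("text_criteria", "lookup_table"))
    return("basis must be 'text_criteria' or 'lookup_table'")
  TRUE
})
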