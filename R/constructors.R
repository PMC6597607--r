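#' Structural parameter names of a model
#'
#' @param model a [ModelSpec].
#' @return `c("cl", "vc", "q", "vp")` for two disposition compartments,
#'   `c("cl", "v")` for one.
#' @export
structuralNames <- function(model) {
  if (model@compartments == 2) c("cl", "vc", "q", "vp") else c("cl", "v")
}

#' Construct a PKStudy from a long-format table
#'
#' @param data a NONMEM-style `data.frame` (see [PKStudy-class]). Missing
#'   `SS`, `II`, `MDV` columns are filled with zeros.
#' @param truth optional list of generating parameters (simulated studies).
#' @return a validated [PKStudy].
#' @export
PKStudy <- function(data, truth = list()) {
  for (col in c("SS", "II", "MDV")) if (is.null(data[[col]])) data[[col]] <- 0
  data <- data[, REQUIRED_COLUMNS]
  obj <- new("PKStudy", data = data, truth = truth)
  validObject(obj)
  obj
}

#' Construct a ModelSpec
#'
#' @param compartments 1 or 2 disposition compartments.
#' @param ka fixed first-order absorption rate constant (1/h).
#' @param dosing `"single"` or `"steady_state"`.
#' @param iiv structural parameters with log-normal inter-individual
#'   variability.
#' @param errorModel `"proportional"` or `"combined"`.
#' @param covariates list of terms built with [covTerm()].
#' @param sexTerms list of terms built with [sexTerm()].
#' @return a validated [ModelSpec].
#' @export
ModelSpec <- function(compartments, ka, dosing = "single", iiv = "cl",
                      errorModel = "proportional", covariates = list(),
                      sexTerms = list()) {
  obj <- new("ModelSpec", compartments = compartments, ka = ka,
             dosing = dosing, iiv = iiv, errorModel = errorModel,
             covariates = covariates, sexTerms = sexTerms)
  validObject(obj)
  obj
}

#' Power covariate term
#'
#' One multiplicative factor `(COV / reference)^exponent` on a structural
#' parameter, with the exponent either estimated (named `theta`) or fixed.
#'
#' @param parameter structural parameter name (e.g. `"cl"`).
#' @param covariate `"weight"` or `"age"`.
#' @param reference the reference (typically median) covariate value; the
#'   typical parameter value applies at this covariate value.
#' @param theta name of the estimated exponent in the [ParameterSet]
#'   (ignored when `fixed` is given).
#' @param fixed a fixed exponent value, or `NULL` to estimate.
#' @return a covariate-term list for [ModelSpec()].
#' @export
covTerm <- function(parameter, covariate, reference, theta = NULL,
                    fixed = NULL) {
  stopifnot(reference > 0)
  list(parameter = parameter, covariate = covariate, reference = reference,
       theta = theta, fixed = fixed)
}

#' Sex covariate term
#'
#' The typical value for girls is a fraction of the typical value for boys;
#' the fraction is the estimated theta named here.
#'
#' @param parameter structural parameter name.
#' @param theta name of the female-to-male fraction in the [ParameterSet].
#' @return a sex-term list for [ModelSpec()].
#' @export
sexTerm <- function(parameter, theta) {
  list(parameter = parameter, theta = theta)
}

#' Construct a ParameterSet
#'
#' @param thetas named positive reals (typical values, covariate exponents,
#'   sex fractions).
#' @param omega2 named non-negative inter-individual variances.
#' @param sigma2prop proportional residual error variance.
#' @param sigma2add additive residual error variance.
#' @param fixed names of entries held fixed during estimation.
#' @return a validated [ParameterSet].
#' @export
ParameterSet <- function(thetas, omega2 = numeric(0), sigma2prop = 0,
                         sigma2add = 0, fixed = character(0)) {
  obj <- new("ParameterSet", thetas = thetas, omega2 = omega2,
             sigma2prop = sigma2prop, sigma2add = sigma2add, fixed = fixed)
  validObject(obj)
  obj
}

#' Construct a ScalingFunction
#'
#' @param clRef reference clearance (L/h).
#' @param wtRef reference body weight (kg), default the typical adult 70 kg.
#' @param exponent allometric exponent, default 0.874 (the pediatric
#'   covariate function for CYP3A-mediated midazolam clearance).
#' @return a validated [ScalingFunction].
#' @export
ScalingFunction <- function(clRef, wtRef = 70, exponent = 0.874) {
  obj <- new("ScalingFunction", clRef = clRef, wtRef = wtRef,
             exponent = exponent)
  validObject(obj)
  obj
}

#' Construct DrugProperties
#'
#' @param name drug name.
#' @param extractionRatio adult hepatic extraction ratio in (0, 1).
#' @param fu adult unbound plasma fraction in (0, 1].
#' @param bindingProtein `"HSA"` or `"AAG"`.
#' @param fCyp3a fraction of metabolism mediated by CYP3A (default 0.75,
#'   the minimum assumed for extrapolation).
#' @return a validated [DrugProperties].
#' @export
DrugProperties <- function(name, extractionRatio, fu, bindingProtein,
                           fCyp3a = 0.75) {
  obj <- new("DrugProperties", name = name, extractionRatio = extractionRatio,
             fu = fu, bindingProtein = bindingProtein, fCyp3a = fCyp3a)
  validObject(obj)
  obj
}

## ---- accessors -----------------------------------------------------------

#' @describeIn PKStudy-class number of subjects
#' @param study a [PKStudy].
#' @export
nSubjects <- function(study) length(unique(study@data$ID))

#' @describeIn PKStudy-class subject identifiers, in order of appearance
#' @export
subjectIds <- function(study) unique(study@data$ID)

#' @describeIn PKStudy-class the underlying long-format table
#' @export
studyData <- function(study) study@data

#' @describeIn PKStudy-class generating parameters of a simulated study
#' @export
studyTruth <- function(study) study@truth

#' @describeIn PKStudy-class number of (non-missing) observations
#' @export
nObservations <- function(study) {
  d <- study@data
  sum(d$EVID == 0 & d$MDV == 0)
}

#' Accessors for fit results
#'
#' @param fit a [FitResult].
#' @return `estimates()` the [ParameterSet]; `ofv()` the objective function
#'   value; `etaMatrix()` the empirical Bayes estimates; `rse()` the
#'   relative standard errors (%).
#' @name fit-accessors
NULL

#' @rdname fit-accessors
#' @export
estimates <- function(fit) fit@estimates

#' @rdname fit-accessors
#' @export
ofv <- function(fit) fit@ofv

#' @rdname fit-accessors
#' @export
etaMatrix <- function(fit) fit@etas

#' @rdname fit-accessors
#' @export
rse <- function(fit) fit@rse

#' @describeIn NpdeResult-class the per-observation npde values
#' @param x an [NpdeResult].
#' @export
npdeValues <- function(x) x@values

## ---- show methods --------------------------------------------------------

setMethod("show", "PKStudy", function(object) {
  d <- object@data
  cat(sprintf("PKStudy: %d subjects, %d observations, %d dose records\n",
              length(unique(d$ID)), sum(d$EVID == 0 & d$MDV == 0),
              sum(d$EVID == 1)))
  cat(sprintf("  weight %.1f kg (%.1f-%.1f), age %.1f y (%.1f-%.1f)\n",
              median(d$WT[!duplicated(d$ID)]), min(d$WT), max(d$WT),
              median(d$AGE[!duplicated(d$ID)]), min(d$AGE), max(d$AGE)))
  if (length(object@truth) > 0) cat("  simulated (truth recorded)\n")
})

setMethod("show", "ModelSpec", function(object) {
  cat(sprintf("ModelSpec: %d-compartment oral (%s dosing), ka = %g 1/h\n",
              object@compartments, object@dosing, object@ka))
  cat(sprintf("  IIV on: %s; %s residual error\n",
              paste(object@iiv, collapse = ", "), object@errorModel))
  for (ct in object@covariates)
    cat(sprintf("  %s ~ (%s/%g)^%s\n", ct$parameter, ct$covariate,
                ct$reference,
                if (is.null(ct$fixed)) ct$theta else paste(ct$fixed, "fix")))
  for (st in object@sexTerms)
    cat(sprintf("  %s: female fraction %s\n", st$parameter, st$theta))
})

setMethod("show", "ParameterSet", function(object) {
  cat("ParameterSet\n  thetas: ",
      paste(sprintf("%s=%.4g", names(object@thetas), object@thetas),
            collapse = ", "), "\n", sep = "")
  if (length(object@omega2))
    cat("  omega2: ",
        paste(sprintf("%s=%.4g", names(object@omega2), object@omega2),
              collapse = ", "), "\n", sep = "")
  cat(sprintf("  sigma2: prop=%.4g add=%.4g\n",
              object@sigma2prop, object@sigma2add))
  if (length(object@fixed))
    cat("  fixed: ", paste(object@fixed, collapse = ", "), "\n", sep = "")
})

setMethod("show", "FitResult", function(object) {
  cat(sprintf("FitResult: OFV = %.3f (%s, %d evaluations)\n", object@ofv,
              if (object@converged) "converged" else "NOT converged",
              object@nEvals))
  show(object@estimates)
})

setMethod("show", "ScalingFunction", function(object) {
  cat(sprintf("ScalingFunction: CL(WT) = %.4g * (WT/%.4g)^%.4g L/h\n",
              object@clRef, object@wtRef, object@exponent))
})

setMethod("show", "BootstrapResult", function(object) {
  cat(sprintf("BootstrapResult: %d/%d resamples converged%s\n",
              object@nConverged, object@nResamples,
              if (object@flagged) " [FLAGGED: >20% non-convergence]" else ""))
  print(data.frame(median = object@median, ci5 = object@ciLower,
                   ci95 = object@ciUpper))
})

setMethod("show", "NpdeResult", function(object) {
  cat(sprintf("NpdeResult: %d observations, %d simulations\n",
              length(object@values), object@nSim))
  print(object@tests)
})

setMethod("show", "AccuracyVerdict", function(object) {
  cat(sprintf("AccuracyVerdict: minimum accurate age class '%s' (%s)\n",
              object@minAgeClass, object@basis))
})
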