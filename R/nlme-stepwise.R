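#' Chi-square threshold for a likelihood-ratio covariate test
#'
#' Upper-tail chi-square quantile: the OFV drop needed for significance at
#' level `alpha` with `df` added parameters. At 1 degree of freedom this is
#' 6.63 for p < 0.01 (forward inclusion) and 7.88 for p < 0.005 (backward
#' deletion).
#'
#' @param alpha significance level in (0, 1).
#' @param df degrees of freedom (>= 1).
#' @return the threshold in OFV points.
#' @export
deltaOFVThreshold <- function(alpha, df = 1) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (df < 1) stop("df must be >= 1")
  qchisq(1 - alpha, df)
}

## candidate bookkeeping: covariate in {weight, age, sex}, parameter a
## structural name. Deterministic order: covariates (weight, age, sex)
## crossed with parameters in structural order.
.candidateGrid <- function(model, covariates, parameters) {
  grid <- expand.grid(parameter = parameters, covariate = covariates,
                      stringsAsFactors = FALSE)
  ord <- order(match(grid$covariate, c("weight", "age", "sex")),
               match(grid$parameter, c("cl", "vc", "v", "vp", "q")))
  grid[ord, , drop = FALSE]
}

.addCandidate <- function(model, init, cand, study) {
  d <- study@data
  first <- !duplicated(d$ID)
  if (cand$covariate == "sex") {
    nm <- paste0(cand$parameter, "_sex")
    model@sexTerms <- c(model@sexTerms, list(sexTerm(cand$parameter, nm)))
    init@thetas[nm] <- 1
  } else {
    nm <- paste0(cand$parameter, "_",
                 switch(cand$covariate, weight = "wt", age = "age"))
    ref <- median(if (cand$covariate == "weight") d$WT[first] else
                    d$AGE[first])
    model@covariates <- c(model@covariates,
                          list(covTerm(cand$parameter, cand$covariate,
                                       reference = ref, theta = nm)))
    init@thetas[nm] <- 0.5
  }
  list(model = model, init = init, theta = nm)
}

## the variance that must shrink for the candidate to be retained: the
## parameter's IIV when it has one, else the residual variance
.relevantVariance <- function(model, params, parameter) {
  if (parameter %in% model@iiv) params@omega2[[parameter]]
  else params@sigma2prop
}

#' Stepwise covariate selection on OFV drops
#'
#' Forward inclusion then backward deletion. At each forward step every
#' remaining candidate (continuous covariates as power terms referenced at
#' the study median, sex as a female fraction) is added to the current
#' model and refit; the candidate with the largest OFV drop is accepted if
#' the drop reaches `forwardDelta` (default 6.63, p < 0.01, 1 df) *and* the
#' relevant variance (the parameter's IIV, or the residual variance when it
#' carries none) decreased. Exact ties keep the earlier candidate in the
#' deterministic (weight, age, sex) x (cl, vc/v, vp, q) order. Backward
#' deletion then removes included covariates one at a time (smallest OFV
#' rise first) as long as the rise does not exceed `backwardDelta`
#' (default 7.88, p < 0.005).
#'
#' @param study a [PKStudy].
#' @param baseModel the covariate-free [ModelSpec] to start from.
#' @param init initial [ParameterSet] for the base model.
#' @param covariates candidate covariates, subset of
#'   `c("weight", "age", "sex")`.
#' @param parameters candidate structural parameters; default all in the
#'   model.
#' @param forwardDelta,backwardDelta OFV thresholds.
#' @param control forwarded to [fitModel()].
#' @return a list with `model`, `init` and `fit` for the selected model,
#'   and `log`, a data.frame recording every tested step (phase, candidate,
#'   OFV change, variance change, decision).
#' @export
stepwiseCovariates <- function(study, baseModel, init,
                               covariates = c("weight", "age", "sex"),
                               parameters = structuralNames(baseModel),
                               forwardDelta = deltaOFVThreshold(0.01, 1),
                               backwardDelta = deltaOFVThreshold(0.005, 1),
                               control = list()) {
  grid <- .candidateGrid(baseModel, covariates, parameters)
  log <- list()
  note <- function(phase, cand, dofv, dvar, decision) {
    log[[length(log) + 1L]] <<- data.frame(
      phase = phase, covariate = cand$covariate, parameter = cand$parameter,
      dOFV = dofv, dVariance = dvar, decision = decision)
  }

  curModel <- baseModel
  curInit <- init
  curFit <- fitModel(study, curModel, curInit, control)
  curEst <- curFit@estimates
  included <- list()
  remaining <- grid
  if (nrow(remaining) > 0) .checkCollinearity(study)

  ## forward inclusion
  repeat {
    if (nrow(remaining) == 0) break
    best <- NULL
    for (i in seq_len(nrow(remaining))) {
      cand <- remaining[i, ]
      trial <- .addCandidate(curModel, curEst, cand, study)
      fit <- fitModel(study, trial$model, trial$init, control)
      dofv <- curFit@ofv - fit@ofv
      dvar <- .relevantVariance(curModel, curEst, cand$parameter) -
        .relevantVariance(trial$model, fit@estimates, cand$parameter)
      eligible <- dofv >= forwardDelta && dvar > 0
      note("forward", cand, dofv,  dvar,
           if (eligible) "eligible" else "rejected")
      if (eligible && (is.null(best) || dofv > best$dofv))
        best <- list(i = i, cand = cand, trial = trial, fit = fit,
                     dofv = dofv)
    }
    if (is.null(best)) break
    note("forward", best$cand, best$dofv, NA, "included")
    curModel <- best$trial$model
    curFit <- best$fit
    curEst <- curFit@estimates
    included <- c(included, list(best$cand))
    remaining <- remaining[-best$i, , drop = FALSE]
  }

  ## backward deletion: sequential single deletion until every remaining
  ## covariate's removal raises the OFV by more than the threshold
  repeat {
    if (length(included) == 0) break
    rises <- numeric(length(included))
    reduced <- vector("list", length(included))
    for (k in seq_along(included)) {
      red <- .dropCandidate(curModel, curEst, included[[k]])
      fit <- fitModel(study, red$model, red$init, control)
      rises[k] <- fit@ofv - curFit@ofv
      reduced[[k]] <- list(model = red$model, fit = fit)
      note("backward", included[[k]], rises[k], NA,
           if (rises[k] > backwardDelta) "retained" else "removable")
    }
    k <- which.min(rises)
    if (rises[k] > backwardDelta) break
    note("backward", included[[k]], rises[k], NA, "removed")
    curModel <- reduced[[k]]$model
    curFit <- reduced[[k]]$fit
    curEst <- curFit@estimates
    included <- included[-k]
  }

  list(model = curModel, init = curEst, fit = curFit,
       included = included, log = do.call(rbind, log))
}

.dropCandidate <- function(model, params, cand) {
  if (cand$covariate == "sex") {
    keep <- vapply(model@sexTerms, function(st)
      st$parameter != cand$parameter, logical(1))
    nm <- paste0(cand$parameter, "_sex")
    model@sexTerms <- model@sexTerms[keep]
  } else {
    nm <- paste0(cand$parameter, "_",
                 switch(cand$covariate, weight = "wt", age = "age"))
    keep <- vapply(model@covariates, function(ct)
      !(identical(ct$parameter, cand$parameter) &&
          identical(ct$covariate, cand$covariate) && identical(ct$theta, nm)),
      logical(1))
    model@covariates <- model@covariates[keep]
  }
  params@thetas <- params@thetas[setdiff(names(params@thetas), nm)]
  list(model = model, init = params)
}

.checkCollinearity <- function(study) {
  d <- study@data
  first <- !duplicated(d$ID)
  if (sum(first) > 2) {
    r <- suppressWarnings(stats::cor(d$WT[first], d$AGE[first]))
    if (is.finite(r) && abs(r) > 0.9)
      message(sprintf(
        "note: weight and age are strongly collinear (r = %.2f); ",
        r), "covariate selection between them is weakly determined")
  }
  invisible(NULL)
}
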