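## Between-drug extrapolation of clearance: the pediatric covariate
## function for CYP3A-mediated midazolam clearance,
## CL_pediatric = CL_adult * (WT / 70)^0.874, applied to adult clearance of
## other CYP3A substrates, with prediction-error accuracy assessment and
## drug-property criteria for when the scaling is systematically accurate.

#' Scale a clearance value by body weight
#'
#' Evaluates `clRef * (wt / wtRef)^exponent`. With the defaults of
#' [ScalingFunction()] (70 kg reference, exponent 0.874) this is the
#' pediatric covariate function for CYP3A-mediated clearance.
#'
#' @param sf a [ScalingFunction].
#' @param wt body weight(s), kg (> 0); vectorized.
#' @return clearance(s) in the units of `clRef`.
#' @examples
#' scaleClearance(ScalingFunction(clRef = 100), wt = 28)  # 44.9 L/h
#' @export
scaleClearance <- function(sf, wt) {
  if (any(wt <= 0)) stop("body weight must be > 0")
  sf@clRef * (wt / sf@wtRef)^sf@exponent
}

#' Signed prediction error of a scaled clearance
#'
#' `PE = (CLscaled - CLref) / CLref * 100%`: positive for overprediction,
#' negative for underprediction. Asymmetric by construction.
#'
#' @param clScaled scaled clearance(s).
#' @param clRef reference clearance(s) (> 0).
#' @return the prediction error(s) in percent.
#' @export
predictionError <- function(clScaled, clRef) {
  if (any(clRef <= 0)) stop("reference clearance must be > 0")
  (clScaled - clRef) / clRef * 100
}

#' Classify a prediction error
#'
#' An absolute PE below 30% is accurate, 30% to below 50% reasonably
#' accurate, and 50% or more inaccurate.
#'
#' @param pe prediction error(s) in percent (finite).
#' @return factor with levels accurate, reasonably_accurate, inaccurate.
#' @export
classifyAccuracy <- function(pe) {
  if (any(!is.finite(pe))) stop("prediction error must be finite")
  a <- abs(pe)
  cls <- ifelse(a < 30, "accurate",
                ifelse(a < 50, "reasonably_accurate", "inaccurate"))
  factor(cls, levels = c("accurate", "reasonably_accurate", "inaccurate"))
}

#' Coefficient of variation of a log-normal variance
#'
#' `CV% = 100 * sqrt(exp(sigma2) - 1)`, the coefficient of variation
#' implied by a log-scale variance (as used for inter-individual
#' variability bands around a typical clearance).
#'
#' @param variance log-scale variance(s), >= 0.
#' @return the CV in percent.
#' @export
cvPercent <- function(variance) {
  if (any(variance < 0)) stop("variance must be >= 0")
  100 * sqrt(exp(variance) - 1)
}

#' Apparent clearance from systemic clearance and bioavailability
#'
#' `CL/F = CL / F`; e.g. a systemic clearance of 41 L/h with an oral
#' bioavailability of 0.41 gives an apparent clearance of 100 L/h.
#'
#' @param clSystemic systemic clearance (L/h).
#' @param f oral bioavailability, in (0, 1].
#' @return apparent oral clearance CL/F (L/h).
#' @export
apparentClearance <- function(clSystemic, f) {
  if (any(f <= 0 | f > 1)) stop("bioavailability must lie in (0, 1]")
  clSystemic / f
}

## extraction-ratio window within which scaling is accurate down to 1 day,
## as a function of fu; NULL when no 1-day criterion applies at this fu
.greenWindow <- function(protein, fu) {
  if (protein == "HSA") {
    ## anchors: fu <= 0.1 -> ER 0.05-0.55; fu >= 0.9 -> ER 0.35-0.65;
    ## linear in fu between, clamped outside
    w <- pmin(1, pmax(0, (fu - 0.1) / 0.8))
    c(0.05 + w * (0.35 - 0.05), 0.55 + w * (0.65 - 0.55))
  } else {
    if (fu >= 0.4) return(NULL)        # no accurate scenarios
    if (fu > 0.1) return(NA)           # no stated criterion
    ## anchors: fu <= 0.025 (>= 97.5% bound) -> ER 0.1-0.5;
    ## fu ~ 0.1 (~90% bound) -> ER 0.4-0.6; linear between
    w <- pmin(1, pmax(0, (fu - 0.025) / 0.075))
    c(0.1 + w * (0.4 - 0.1), 0.5 + w * (0.6 - 0.5))
  }
}

#' Minimum age of accurate between-drug clearance scaling
#'
#' Applies the drug-property criteria for when the pediatric covariate
#' function for midazolam clearance scales a CYP3A substrate's clearance
#' accurately down to neonates (1 day): for HSA-bound substrates the adult
#' extraction ratio must fall in a window running linearly from 0.05-0.55
#' at high protein binding (fu <= 0.1) to 0.35-0.65 at low binding
#' (fu >= 0.9); for AAG-bound substrates no scenario is accurate at
#' fu >= 0.4, while the window runs from 0.1-0.5 at fu <= 0.025 to 0.4-0.6
#' at fu around 0.1. CYP3A must account for at least 75% of metabolism, or
#' the verdict is indeterminate.
#'
#' Outside the 1-day criteria, an optional user-supplied lookup grid
#' (columns `protein`, `fu_min`, `fu_max`, `er_min`, `er_max`,
#' `age_class`) assigns the finer age classes; without a matching grid row
#' the verdict is indeterminate.
#'
#' @param props a [DrugProperties].
#' @param grid optional lookup `data.frame` as described above.
#' @return an [AccuracyVerdict].
#' @export
minAccurateAge <- function(props, grid = NULL) {
  validObject(props)
  if (props@fCyp3a < 0.75) {
    warning("fCyp3a < 0.75: the extrapolation criteria assume CYP3A ",
            "mediates at least 75% of metabolism")
    return(new("AccuracyVerdict", minAgeClass = "indeterminate",
               basis = "text_criteria"))
  }
  win <- .greenWindow(props@bindingProtein, props@fu)
  if (!is.null(win) && !anyNA(win) &&
      props@extractionRatio >= win[1] && props@extractionRatio <= win[2])
    return(new("AccuracyVerdict", minAgeClass = "1 day",
               basis = "text_criteria"))
  if (!is.null(grid)) {
    need <- c("protein", "fu_min", "fu_max", "er_min", "er_max", "age_class")
    if (!all(need %in% names(grid)))
      stop("malformed grid: need columns ", paste(need, collapse = ", "))
    hit <- grid$protein == props@bindingProtein &
      props@fu >= grid$fu_min & props@fu <= grid$fu_max &
      props@extractionRatio >= grid$er_min &
      props@extractionRatio <= grid$er_max
    if (any(hit)) {
      cls <- grid$age_class[which(hit)[1]]
      if (!cls %in% AGE_CLASSES) stop("malformed grid: unknown age class ", cls)
      return(new("AccuracyVerdict", minAgeClass = cls,
                 basis = "lookup_table"))
    }
  }
  new("AccuracyVerdict", minAgeClass = "indeterminate",
      basis = "text_criteria")
}

#' Prediction-error report for typical pediatric subjects
#'
#' For each drug, scales the adult clearance to the requested body weights
#' with the extrapolation function and compares against the drug's
#' pediatric reference covariate function, reporting the signed prediction
#' error (rounded to one decimal in the `pe` column) and its accuracy
#' class.
#'
#' @param drugs `data.frame` with columns `name`, `cl_adult` (L/h),
#'   `ref_cl` (pediatric reference clearance at `ref_wt`), `ref_wt` (kg)
#'   and `ref_exp` (reference allometric exponent).
#' @param weights body weights of the typical subjects (kg); default the
#'   10 kg infant, 20 kg child and 50 kg adolescent.
#' @param wtRef,exponent the extrapolation function (defaults 70 kg and
#'   0.874).
#' @return a long `data.frame`: name, weight, cl_scaled, cl_ref, pe,
#'   accuracy.
#' @export
peReport <- function(drugs, weights = c(10, 20, 50), wtRef = 70,
                     exponent = 0.874) {
  need <- c("name", "cl_adult", "ref_cl", "ref_wt", "ref_exp")
  if (!all(need %in% names(drugs)))
    stop("drugs table needs columns ", paste(need, collapse = ", "))
  rows <- list()
  for (i in seq_len(nrow(drugs))) {
    sf <- ScalingFunction(drugs$cl_adult[i], wtRef, exponent)
    ref <- ScalingFunction(drugs$ref_cl[i], drugs$ref_wt[i],
                           drugs$ref_exp[i])
    sc <- scaleClearance(sf, weights)
    rf <- scaleClearance(ref, weights)
    pe <- predictionError(sc, rf)
    rows[[i]] <- data.frame(name = drugs$name[i], weight = weights,
                            cl_scaled = sc, cl_ref = rf,
                            pe = round(pe, 1),
                            accuracy = classifyAccuracy(pe))
  }
  do.call(rbind, rows)
}
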