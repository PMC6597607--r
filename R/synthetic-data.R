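## Synthetic study generators. The two presets emulate the designs of the
## studies behind the package's reference parameterizations: a dense
## single-oral-dose pediatric midazolam study (31 patients, 8-11 samples on
## a nominal 0.25-22 h grid) and a sparse steady-state pediatric sildenafil
## study (156 patients, 1-4 samples at trough and ~3/6/8 h post-dose, with
## weight-stratified dose groups). Weights are log-uniform over the
## published ranges; age is a monotone map of weight (with log-normal
## jitter) chosen to land near the published median ages. The generating
## parameters are recorded in the study's `truth` slot.

#' Reference parameter set of the pediatric midazolam model
#'
#' Two-compartment oral model in apparent parameters, referenced at the
#' 30.2 kg median weight: CL/F 102.6 L/h (weight exponent 0.874), Vc/F
#' 156 L (exponent 1.88), Vp/F 255 L (exponent 0.91), Q/F 121.8 L/h
#' (exponent fixed at 0.75), ka fixed at 3.5 1/h, IIV variances 0.158 (CL)
#' and 1.19 (Vc), proportional error variance 0.283.
#'
#' @return a [ParameterSet].
#' @export
midazolamTruth <- function() {
  ParameterSet(
    thetas = c(cl = 102.6, cl_wt = 0.874, vc = 156, vc_wt = 1.88,
               vp = 255, vp_wt = 0.91, q = 121.8),
    omega2 = c(cl = 0.158, vc = 1.19),
    sigma2prop = 0.283)
}

#' @describeIn midazolamTruth the matching [ModelSpec] (weight on all four
#'   structural parameters; the Q/F exponent fixed at 0.75).
#' @param refWeight reference body weight of the covariate terms (kg).
#' @export
midazolamModel <- function(refWeight = 30.2) {
  ModelSpec(
    compartments = 2, ka = 3.5, dosing = "single", iiv = c("cl", "vc"),
    errorModel = "proportional",
    covariates = list(
      covTerm("cl", "weight", refWeight, theta = "cl_wt"),
      covTerm("vc", "weight", refWeight, theta = "vc_wt"),
      covTerm("vp", "weight", refWeight, theta = "vp_wt"),
      covTerm("q", "weight", refWeight, fixed = 0.75)))
}

#' Reference parameter set of the pediatric sildenafil model
#'
#' One-compartment oral steady-state model: CL/F 113 L/h referenced at
#' 70 kg (weight exponent 1.08), V/F 540 L referenced at 28 kg (exponent
#' 3.18), ka fixed at 1 1/h, IIV variance 0.493 on CL, proportional error
#' variance 0.627.
#'
#' @return a [ParameterSet].
#' @export
sildenafilTruth <- function() {
  ParameterSet(
    thetas = c(cl = 113, cl_wt = 1.08, v = 540, v_wt = 3.18),
    omega2 = c(cl = 0.493),
    sigma2prop = 0.627)
}

#' @describeIn sildenafilTruth the matching [ModelSpec] (clearance
#'   referenced at 70 kg, volume at 28 kg).
#' @export
sildenafilModel <- function() {
  ModelSpec(
    compartments = 1, ka = 1, dosing = "steady_state", iiv = "cl",
    errorModel = "proportional",
    covariates = list(
      covTerm("cl", "weight", 70, theta = "cl_wt"),
      covTerm("v", "weight", 28, theta = "v_wt")))
}

## weight -> age map: monotone, hits ~8 y at ~30 kg, clamped to the 1-17 y
## study range; multiplicative log-normal jitter when sd > 0
.ageFromWeight <- function(wt, sd = 0.15) {
  age <- (wt - 8) / 2.8
  if (sd > 0) age <- age * exp(rnorm(length(wt), 0, sd))
  pmin(17, pmax(1, age))
}

.truthList <- function(params, model) {
  list(thetas = as.list(params@thetas), omega2 = as.list(params@omega2),
       sigma2prop = params@sigma2prop, sigma2add = params@sigma2add,
       ka = model@ka, compartments = model@compartments,
       dosing = model@dosing)
}

#' Simulate a dense single-dose midazolam-like study
#'
#' 31 subjects by default: weights log-uniform on 9.5-83.2 kg, a single
#' oral dose at t = 0 of about 0.45 mg/kg rounded to 0.5 mg and clamped to
#' 3-15 mg (median near 12.5 mg), 8-11 of the 11 nominal sampling times
#' (0.25, 0.5, 1, 1.5, 2, 3, 4, 6, 8, 10, 22 h, each jittered by +/-10%)
#' retained per subject, and concentrations generated from the
#' two-compartment model with log-normal IIV and the proportional/additive
#' residual model. With an additive error component enabled, negative
#' simulated concentrations are truncated at zero and flagged in the truth
#' record; with proportional-only error they are kept so that refitting the
#' generating model remains consistent.
#'
#' @param seed integer seed; the same seed reproduces the dataset exactly.
#' @param truth generating [ParameterSet] (default [midazolamTruth()]).
#' @param model generating [ModelSpec] (default [midazolamModel()]).
#' @param n number of subjects.
#' @param weightRange log-uniform sampling range for body weight (kg).
#' @param femaleFraction probability a subject is female.
#' @param timeJitter relative uniform jitter on the nominal times.
#' @return a [PKStudy] with the truth recorded.
#' @export
simulateMidazolamStudy <- function(seed, truth = midazolamTruth(),
                                   model = midazolamModel(), n = 31,
                                   weightRange = c(9.5, 83.2),
                                   femaleFraction = 0.52,
                                   timeJitter = 0.1) {
  nominal <- c(0.25, 0.5, 1, 1.5, 2, 3, 4, 6, 8, 10, 22)
  .withSeed(seed, {
    wt <- exp(runif(n, log(weightRange[1]), log(weightRange[2])))
    age <- .ageFromWeight(wt)
    sex <- rbinom(n, 1, femaleFraction)
    dose <- pmin(15, pmax(3, round(0.45 * wt / 0.5) * 0.5))
    rows <- vector("list", n)
    truncated <- 0L
    for (i in seq_len(n)) {
      nSamp <- sample(8:11, 1, prob = c(0.15, 0.2, 0.35, 0.3))
      keep <- sort(sample(seq_along(nominal), nSamp))
      times <- nominal[keep] * runif(nSamp, 1 - timeJitter, 1 + timeJitter)
      subj <- list(weight = wt[i], age = age[i], sex = sex[i],
                   dose = dose[i], tau = -1, times = times, n = nSamp)
      y <- .simulateSubject(model, truth, subj)
      if (truth@sigma2add > 0 && any(y < 0)) {
        truncated <- truncated + sum(y < 0)
        y[y < 0] <- 0
      }
      rows[[i]] <- data.frame(
        ID = i, TIME = c(0, times), AMT = c(dose[i], rep(0, nSamp)),
        EVID = c(1, rep(0, nSamp)), SS = 0, II = 0,
        DV = c(NA, y), MDV = c(1, rep(0, nSamp)),
        WT = wt[i], AGE = age[i], SEX = sex[i])
    }
    tr <- .truthList(truth, model)
    tr$truncated_negative <- truncated
    PKStudy(do.call(rbind, rows), truth = tr)
  })
}

## weight-stratified dose per the sparse steady-state design: medium doses
## 10/20/40 mg and high doses 20/40/80 mg for <=20 / 20-45 / >45 kg; low
## dose 10 mg only for subjects > 20 kg
.sildenafilDose <- function(wt, group) {
  stratum <- findInterval(wt, c(20, 45), left.open = TRUE) + 1L
  switch(group,
         low = 10,
         med = c(10, 20, 40)[stratum],
         high = c(20, 40, 80)[stratum])
}

#' Simulate a sparse steady-state sildenafil-like study
#'
#' 156 subjects by default: weights log-uniform on 8.2-106 kg; subjects are
#' assigned to low/medium/high dose groups with the configured sizes, with
#' the constraint that subjects of 20 kg or less never receive the low dose
#' (they are swapped with a heavier medium/high subject so the group sizes
#' are preserved); doses follow the weight-stratified rule (medium
#' 10/20/40 mg, high 20/40/80 mg for <=20 / 20-45 / >45 kg, low 10 mg);
#' each subject contributes 1-4 steady-state samples (median 4) at the
#' trough and around 3, 6 and 8 h post-dose; and concentrations come from
#' the steady-state one-compartment model with IIV on clearance and
#' proportional error.
#'
#' @inheritParams simulateMidazolamStudy
#' @param truth generating [ParameterSet] (default [sildenafilTruth()]).
#' @param model generating [ModelSpec] (default [sildenafilModel()]).
#' @param groupSizes subjects in the (low, medium, high) dose groups;
#'   must sum to `n`.
#' @param tau dosing interval (h); the study sampled at trough and up to
#'   8 h post-dose, implying an interval of at most 8 h.
#' @param femaleFraction probability a subject is female.
#' @return a [PKStudy] with the truth recorded.
#' @export
simulateSildenafilStudy <- function(seed, truth = sildenafilTruth(),
                                    model = sildenafilModel(), n = 156,
                                    groupSizes = c(39, 48, 69), tau = 8,
                                    weightRange = c(8.2, 106),
                                    femaleFraction = 0.63,
                                    timeJitter = 0.1) {
  stopifnot(sum(groupSizes) == n)
  nominal <- c(0, 3, 6, 8 / 8 * tau)
  .withSeed(seed, {
    wt <- exp(runif(n, log(weightRange[1]), log(weightRange[2])))
    age <- .ageFromWeight(wt)
    sex <- rbinom(n, 1, femaleFraction)
    group <- sample(rep(c("low", "med", "high"), groupSizes))
    ## subjects <= 20 kg cannot be in the low-dose group: swap each with a
    ## random heavier subject from medium/high, preserving group sizes
    bad <- which(group == "low" & wt <= 20)
    for (i in bad) {
      pool <- which(group != "low" & wt > 20)
      if (length(pool) == 0) { group[i] <- sample(c("med", "high"), 1); next }
      j <- pool[sample.int(length(pool), 1)]
      tmp <- group[i]; group[i] <- group[j]; group[j] <- tmp
    }
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      dose <- .sildenafilDose(wt[i], group[i])
      nSamp <- sample(1:4, 1, prob = c(0.05, 0.1, 0.2, 0.65))
      keep <- sort(sample(seq_along(nominal), nSamp))
      times <- nominal[keep]
      jit <- times > 0
      times[jit] <- pmin(tau, times[jit] *
                           runif(sum(jit), 1 - timeJitter, 1 + timeJitter))
      subj <- list(weight = wt[i], age = age[i], sex = sex[i],
                   dose = dose, tau = tau, times = times, n = nSamp)
      y <- .simulateSubject(model, truth, subj)
      rows[[i]] <- data.frame(
        ID = i, TIME = c(0, times), AMT = c(dose, rep(0, nSamp)),
        EVID = c(1, rep(0, nSamp)), SS = c(1, rep(0, nSamp)),
        II = c(tau, rep(0, nSamp)),
        DV = c(NA, y), MDV = c(1, rep(0, nSamp)),
        WT = wt[i], AGE = age[i], SEX = sex[i])
    }
    tr <- .truthList(truth, model)
    tr$tau <- tau
    tr$groups <- as.list(table(group))
    PKStudy(do.call(rbind, rows), truth = tr)
  })
}
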