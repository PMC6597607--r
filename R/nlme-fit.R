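## Marginal-likelihood machinery. The estimation target is the Laplace
## approximation with interaction: per subject, the joint -2 log density of
## (observations, eta) is minimized over eta (quasi-Newton from eta = 0,
## gradient tolerance 1e-8), and the marginal -2 log-likelihood is the
## Laplace expansion at that conditional mode, with the residual variance
## evaluated at the individual prediction (the "interaction"). Evaluated at
## the conditional mode this is the FOCE-I objective family; both method
## names are accepted and map to the same computation. Full 2*pi constants
## are included so the objective is comparable with quadrature.

.modelCode <- function(model) {
  if (model@compartments == 2) 1L
  else if (model@dosing == "steady_state") 2L
  else 3L
}

## Split a study into per-subject records used by the likelihood kernels.
.subjectList <- function(study, model) {
  d <- study@data
  ids <- unique(d$ID)
  lapply(ids, function(id) {
    rows <- d[d$ID == id, , drop = FALSE]
    doses <- rows[rows$EVID == 1, , drop = FALSE]
    obs <- rows[rows$EVID == 0 & rows$MDV == 0, , drop = FALSE]
    if (nrow(doses) == 0)
      stop("subject ", id, " has no dose record")
    tau <- if (model@dosing == "steady_state") doses$II[1] else -1
    list(id = id, weight = rows$WT[1], age = rows$AGE[1], sex = rows$SEX[1],
         dose = doses$AMT[1], tau = tau, times = obs$TIME, y = obs$DV,
         n = nrow(obs))
  })
}

## Covariate-adjusted typical structural parameters for one subject.
.typicalStructural <- function(model, params, subj) {
  pnames <- structuralNames(model)
  th <- params@thetas
  out <- numeric(length(pnames))
  names(out) <- pnames
  for (p in pnames) {
    if (is.na(th[p]))
      stop("ParameterSet lacks a typical value for '", p, "'")
    val <- th[[p]]
    for (ct in model@covariates) {
      if (ct$parameter != p) next
      cov <- switch(ct$covariate, weight = subj$weight, age = subj$age)
      expo <- if (!is.null(ct$fixed)) ct$fixed else th[[ct$theta]]
      val <- val * (cov / ct$reference)^expo
    }
    for (st in model@sexTerms) {
      if (st$parameter != p) next
      if (subj$sex == 1) val <- val * th[[st$theta]]
    }
    out[p] <- val
  }
  out
}

## 0-based eta index per structural parameter (-1 = no random effect).
.etaMap <- function(model) {
  pnames <- structuralNames(model)
  m <- match(pnames, model@iiv) - 1L
  m[is.na(m)] <- -1L
  m
}

.subjectLaplace <- function(model, params, subj, etaStart = NULL,
                            tol = 1e-8, maxit = 200L) {
  q <- length(model@iiv)
  if (is.null(etaStart)) etaStart <- rep(0, q)
  omega2 <- params@omega2[model@iiv]
  ptyp <- .typicalStructural(model, params, subj)
  cpp_subject_laplace(subj$times, subj$y, subj$dose, subj$tau,
                      .modelCode(model), model@ka, ptyp, .etaMap(model),
                      as.numeric(omega2), params@sigma2prop,
                      params@sigma2add, etaStart, tol, maxit)
}

#' Marginal objective function value (-2 log-likelihood)
#'
#' Approximate marginal -2 log-likelihood of a population model, additive
#' over subjects. Inter-individual random effects are integrated out by a
#' Laplace expansion at the per-subject conditional mode with interaction
#' (eta-dependent residual variance); `"focei"` and `"laplace"` name the
#' same computation. The 2*pi constants are included.
#'
#' @param study a [PKStudy].
#' @param model a [ModelSpec].
#' @param params a [ParameterSet].
#' @param method `"focei"` (default) or `"laplace"`.
#' @return the objective function value (scalar).
#' @export
marginalOFV <- function(study, model, params, method = c("focei", "laplace")) {
  match.arg(method)
  sum(.ofvDetail(study, model, params)$perSubject)
}

## Flattened per-subject data reused across objective evaluations.
.studyCache <- function(study, model) {
  subjects <- .subjectList(study, model)
  list(subjects = subjects,
       ids = sapply(subjects, function(s) as.character(s$id)),
       obsStart = as.integer(c(0, cumsum(vapply(subjects, function(s) s$n,
                                                numeric(1))))),
       t = as.numeric(unlist(lapply(subjects, `[[`, "times"))),
       y = as.numeric(unlist(lapply(subjects, `[[`, "y"))),
       dose = vapply(subjects, `[[`, numeric(1), "dose"),
       tau = vapply(subjects, function(s) as.numeric(s$tau), numeric(1)),
       weight = vapply(subjects, `[[`, numeric(1), "weight"),
       age = vapply(subjects, `[[`, numeric(1), "age"),
       sex = vapply(subjects, function(s) as.numeric(s$sex), numeric(1)))
}

## (npar x nsub) matrix of covariate-adjusted typical structural values
.typicalMatrix <- function(model, params, cache) {
  pnames <- structuralNames(model)
  th <- params@thetas
  nsub <- length(cache$dose)
  out <- matrix(0, length(pnames), nsub)
  for (k in seq_along(pnames)) {
    p <- pnames[k]
    if (is.na(th[p]))
      stop("ParameterSet lacks a typical value for '", p, "'")
    val <- rep(th[[p]], nsub)
    for (ct in model@covariates) {
      if (ct$parameter != p) next
      cov <- switch(ct$covariate, weight = cache$weight, age = cache$age)
      expo <- if (!is.null(ct$fixed)) ct$fixed else th[[ct$theta]]
      val <- val * (cov / ct$reference)^expo
    }
    for (st in model@sexTerms) {
      if (st$parameter != p) next
      val <- val * ifelse(cache$sex == 1, th[[st$theta]], 1)
    }
    out[k, ] <- val
  }
  out
}

.ofvCached <- function(model, params, cache, tol = 1e-8, maxit = 200L) {
  cpp_study_laplace(cache$obsStart, cache$t, cache$y, cache$dose, cache$tau,
                    .modelCode(model), model@ka,
                    .typicalMatrix(model, params, cache), .etaMap(model),
                    as.numeric(params@omega2[model@iiv]), params@sigma2prop,
                    params@sigma2add, tol, maxit)
}

.ofvDetail <- function(study, model, params, cache = NULL) {
  if (is.null(cache)) cache <- .studyCache(study, model)
  res <- .ofvCached(model, params, cache)
  if (any(!is.finite(res$perSubject))) {
    bad <- which(!is.finite(res$perSubject))[1]
    stop("non-finite marginal likelihood for subject ", cache$ids[bad])
  }
  etas <- res$etas
  dimnames(etas) <- list(cache$ids, model@iiv)
  list(ofv = res$ofv, perSubject = res$perSubject, etas = etas)
}

## ---- free-parameter packing ---------------------------------------------

## Typical values, sex fractions and variances are estimated on the log
## scale (positivity by construction); covariate exponents on the identity
## scale (their sign is data-determined).
.freeTable <- function(model, init) {
  expNames <- unlist(lapply(model@covariates, function(ct) ct$theta))
  rows <- list()
  for (nm in names(init@thetas)) {
    if (nm %in% init@fixed) next
    rows[[length(rows) + 1L]] <- data.frame(
      name = nm, kind = "theta",
      trans = if (nm %in% expNames) "identity" else "log")
  }
  for (nm in names(init@omega2)) {
    key <- paste0("omega2.", nm)
    if (key %in% init@fixed) next
    if (init@omega2[[nm]] <= 0)
      stop("free IIV variance '", nm, "' must start > 0 (or be fixed)")
    rows[[length(rows) + 1L]] <- data.frame(name = key, kind = "omega2",
                                            trans = "log")
  }
  if (!"sigma2prop" %in% init@fixed)
    rows[[length(rows) + 1L]] <- data.frame(name = "sigma2prop",
                                            kind = "sigma2", trans = "log")
  if (model@errorModel == "combined" && !"sigma2add" %in% init@fixed)
    rows[[length(rows) + 1L]] <- data.frame(name = "sigma2add",
                                            kind = "sigma2", trans = "log")
  do.call(rbind, rows)
}

.getFree <- function(params, tab) {
  vapply(seq_len(nrow(tab)), function(i) {
    nm <- tab$name[i]
    v <- switch(tab$kind[i],
                theta = params@thetas[[nm]],
                omega2 = params@omega2[[sub("^omega2\\.", "", nm)]],
                sigma2 = slot(params, nm))
    if (tab$trans[i] == "log") log(v) else v
  }, numeric(1))
}

.setFree <- function(params, tab, x) {
  for (i in seq_len(nrow(tab))) {
    v <- if (tab$trans[i] == "log") exp(x[i]) else x[i]
    nm <- tab$name[i]
    if (tab$kind[i] == "theta") params@thetas[[nm]] <- v
    else if (tab$kind[i] == "omega2")
      params@omega2[[sub("^omega2\\.", "", nm)]] <- v
    else slot(params, nm) <- v
  }
  params
}

#' Fit a population PK model by approximate maximum likelihood
#'
#' Minimizes [marginalOFV()] over the free parameters with a quasi-Newton
#' optimizer ([stats::nlminb]); typical values and variances are optimized
#' on the log scale, covariate exponents untransformed. Relative standard
#' errors come from a central finite-difference Hessian of the objective at
#' the optimum (moderate relative steps), using that the inverse of half the
#' -2 log-likelihood Hessian estimates the sampling covariance.
#'
#' @param study a [PKStudy].
#' @param model a [ModelSpec].
#' @param init initial [ParameterSet]; entries listed in its `fixed` slot
#'   are held at their initial values.
#' @param control list: `rel.tol` (default 1e-6), `iter.max` (500),
#'   `eval.max` (4000) forwarded to the outer optimizer.
#' @return a [FitResult] (with `converged = FALSE` and the best-found state
#'   on non-convergence).
#' @export
fitModel <- function(study, model, init, control = list()) {
  tab <- .freeTable(model, init)
  if (nSubjects(study) < length(model@iiv))
    warning("fewer subjects than IIV terms: the design is weakly identified")
  cache <- .studyCache(study, model)
  nEvals <- 0L
  objective <- function(x) {
    nEvals <<- nEvals + 1L
    p <- .setFree(init, tab, x)
    v <- tryCatch(.ofvCached(model, p, cache)$ofv, error = function(e) NaN)
    if (!is.finite(v)) 1e10 else v
  }
  ctrl <- list(rel.tol = control$rel.tol %||% 1e-6,
               iter.max = control$iter.max %||% 500L,
               eval.max = control$eval.max %||% 4000L)
  ## The inner eta optimization leaves the objective with small kinks
  ## (conditional modes can jump between nearby solutions), which can stall
  ## a pure gradient-based outer optimizer. Alternate quasi-Newton passes
  ## with a simplex refinement until the OFV is stable; declare convergence
  ## on a fixed point (cycle improvement below 0.01 OFV units).
  opt <- nlminb(.getFree(init, tab), objective, control = ctrl)
  best <- list(par = opt$par, value = opt$objective)
  converged <- FALSE
  for (r in seq_len(control$cycles %||% 3L)) {
    nm <- stats::optim(best$par, objective, method = "Nelder-Mead",
                       control = list(maxit = 600, reltol = 1e-8))
    opt2 <- nlminb(nm$par, objective, control = ctrl)
    value <- min(nm$value, opt2$objective)
    par <- if (opt2$objective <= nm$value) opt2$par else nm$par
    delta <- best$value - value
    if (value <= best$value) best <- list(par = par, value = value)
    if (abs(delta) < 0.01) {
      converged <- TRUE
      break
    }
  }
  est <- .setFree(init, tab, best$par)
  detail <- .ofvDetail(study, model, est, cache)
  rseOut <- .rseFromHessian(model, est, tab, cache)
  new("FitResult", estimates = est, ofv = detail$ofv, rse = rseOut,
      etas = detail$etas, converged = converged,
      nEvals = nEvals, model = model)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## RSE (%) via a central finite-difference Hessian of the OFV on the
## untransformed scale; Cov = 2 * H^-1 since OFV = -2 log L.
.rseFromHessian <- function(model, est, tab, cache) {
  vals <- vapply(seq_len(nrow(tab)), function(i) {
    nm <- tab$name[i]
    switch(tab$kind[i],
           theta = est@thetas[[nm]],
           omega2 = est@omega2[[sub("^omega2\\.", "", nm)]],
           sigma2 = slot(est, nm))
  }, numeric(1))
  names(vals) <- tab$name
  f <- function(v) {
    p <- est
    for (i in seq_len(nrow(tab))) {
      nm <- tab$name[i]
      if (tab$kind[i] == "theta") p@thetas[[nm]] <- v[i]
      else if (tab$kind[i] == "omega2")
        p@omega2[[sub("^omega2\\.", "", nm)]] <- v[i]
      else slot(p, nm) <- v[i]
    }
    tryCatch(.ofvCached(model, p, cache)$ofv, error = function(e) NA_real_)
  }
  k <- length(vals)
  ## moderate relative steps: the objective carries small kinks where
  ## conditional modes shift, so tiny steps would amplify them
  h <- pmax(abs(vals) * 0.05, 1e-4)
  H <- matrix(NA_real_, k, k)
  f0 <- f(vals)
  ok <- is.finite(f0)
  if (ok) {
    for (i in seq_len(k)) {
      vp <- vals; vp[i] <- vals[i] + h[i]
      vm <- vals; vm[i] <- vals[i] - h[i]
      H[i, i] <- (f(vp) - 2 * f0 + f(vm)) / h[i]^2
    }
    if (k > 1) {
      for (i in seq_len(k - 1)) for (j in seq((i + 1), k)) {
        vpp <- vals; vpp[c(i, j)] <- vals[c(i, j)] + h[c(i, j)]
        vpm <- vals; vpm[i] <- vals[i] + h[i]; vpm[j] <- vals[j] - h[j]
        vmp <- vals; vmp[i] <- vals[i] - h[i]; vmp[j] <- vals[j] + h[j]
        vmm <- vals; vmm[c(i, j)] <- vals[c(i, j)] - h[c(i, j)]
        H[i, j] <- H[j, i] <-
          (f(vpp) - f(vpm) - f(vmp) + f(vmm)) / (4 * h[i] * h[j])
      }
    }
  }
  rsev <- rep(NA_real_, k)
  names(rsev) <- tab$name
  covm <- tryCatch(2 * solve(H), error = function(e) NULL)
  if (!is.null(covm)) {
    dg <- diag(covm)
    good <- is.finite(dg) & dg > 0
    rsev[good] <- 100 * sqrt(dg[good]) / abs(vals[good])
  }
  rsev
}

#' Empirical Bayes estimates of the random effects
#'
#' Per-subject maximizer of the conditional joint density of (data, eta)
#' at the supplied population parameters. A subject without observations
#' gets the prior mode eta = 0, and eta shrinks to 0 as omega2 tends to 0.
#'
#' @param study a [PKStudy].
#' @param model a [ModelSpec].
#' @param params a [ParameterSet] (typically from a converged fit).
#' @param id optional single subject id; default all subjects.
#' @return a named eta vector for one subject, or a subjects x effects
#'   matrix (zero columns when the model has no IIV terms).
#' @export
empiricalBayes <- function(study, model, params, id = NULL) {
  subjects <- .subjectList(study, model)
  q <- length(model@iiv)
  if (!is.null(id)) {
    keep <- vapply(subjects, function(s) s$id == id, logical(1))
    if (!any(keep)) stop("unknown subject id: ", id)
    subjects <- subjects[keep]
  }
  out <- matrix(0, length(subjects), q,
                dimnames = list(sapply(subjects, function(s) as.character(s$id)),
                                model@iiv))
  for (i in seq_along(subjects)) {
    if (q == 0 || subjects[[i]]$n == 0) next
    res <- .subjectLaplace(model, params, subjects[[i]])
    if (!isTRUE(res$converged))
      stop("inner eta optimization failed for subject ", subjects[[i]]$id)
    out[i, ] <- res$eta
  }
  if (!is.null(id)) out[1, ] else out
}

## individual prediction for a subject at a given eta
.predSubject <- function(model, params, subj, eta) {
  ptyp <- .typicalStructural(model, params, subj)
  emap <- .etaMap(model)
  p <- ptyp * exp(ifelse(emap >= 0, eta[emap + 1L], 0))
  code <- .modelCode(model)
  if (code == 1L) cpp_conc2cmt(subj$dose, subj$times, p[1], p[2], p[3], p[4],
                               model@ka)
  else if (code == 2L) cpp_conc1cmt_ss(subj$dose, subj$tau, subj$times,
                                       p[1], p[2], model@ka)
  else cpp_conc1cmt(subj$dose, subj$times, p[1], p[2], model@ka)
}

#' Conditional weighted residuals (CWRES)
#'
#' FOCE-linearized standardized residuals: per subject, the model is
#' linearized in eta at the empirical Bayes estimate, the marginal
#' covariance `G Omega G' + diag(sigma2prop * f^2 + sigma2add)` is formed,
#' and the population-corrected residual `y - (f - G etahat)` is
#' decorrelated with its Cholesky factor. Approximately standard normal
#' under the true model.
#'
#' @param study a [PKStudy].
#' @param model a [ModelSpec].
#' @param fit a converged [FitResult], or a [ParameterSet].
#' @return `data.frame` with columns ID, TIME, CWRES (one row per
#'   observation).
#' @export
cwres <- function(study, model, fit) {
  params <- if (is(fit, "FitResult")) fit@estimates else fit
  subjects <- .subjectList(study, model)
  q <- length(model@iiv)
  omega <- diag(as.numeric(params@omega2[model@iiv]), q)
  out <- vector("list", length(subjects))
  for (i in seq_along(subjects)) {
    s <- subjects[[i]]
    if (s$n == 0) next
    eta <- if (q > 0) .subjectLaplace(model, params, s)$eta else numeric(0)
    f0 <- .predSubject(model, params, s, eta)
    G <- matrix(0, s$n, q)
    h <- 1e-4
    for (k in seq_len(q)) {
      ep <- eta; ep[k] <- eta[k] + h
      em <- eta; em[k] <- eta[k] - h
      G[, k] <- (.predSubject(model, params, s, ep) -
                 .predSubject(model, params, s, em)) / (2 * h)
    }
    V <- diag(params@sigma2prop * f0^2 + params@sigma2add, s$n)
    if (q > 0) V <- V + G %*% omega %*% t(G)
    L <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(L))
      stop("singular conditional covariance for subject ", s$id)
    r <- s$y - (f0 - if (q > 0) as.numeric(G %*% eta) else 0)
    w <- forwardsolve(t(L), r)
    out[[i]] <- data.frame(ID = s$id, TIME = s$times, CWRES = w)
  }
  do.call(rbind, out)
}
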