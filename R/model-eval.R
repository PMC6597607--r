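## Simulation-based model evaluation: nonparametric bootstrap for parameter
## precision, and normalized prediction distribution errors (NPDE) for
## predictive performance.

## free-parameter values of a ParameterSet as a named vector (report scale)
.paramVector <- function(model, params) {
  v <- params@thetas
  if (length(params@omega2))
    v <- c(v, setNames(params@omega2, paste0("omega2.", names(params@omega2))))
  v <- c(v, sigma2prop = params@sigma2prop)
  if (model@errorModel == "combined") v <- c(v, sigma2add = params@sigma2add)
  v
}

#' Nonparametric bootstrap of a population PK fit
#'
#' Resamples subjects with replacement (preserving the study size), refits
#' each resample starting from the original estimates, and summarizes the
#' converged replicates by the median and the 5th/95th percentiles (the 90%
#' confidence interval). Percentiles use linear interpolation between order
#' statistics ([stats::quantile] type 7). Reproducible for a given seed.
#'
#' @param study a [PKStudy].
#' @param model a [ModelSpec].
#' @param fit the converged base [FitResult].
#' @param n number of resamples (default 250).
#' @param seed integer seed.
#' @param control forwarded to [fitModel()].
#' @return a [BootstrapResult]; flagged (not discarded) when more than 20%
#'   of the resamples failed to converge.
#' @export
bootstrapFit <- function(study, model, fit, n = 250, seed, control = list()) {
  if (!fit@converged) stop("bootstrap requires a converged base fit")
  ids <- subjectIds(study)
  d <- study@data
  est <- fit@estimates
  draws <- .withSeed(seed, replicate(n, sample(ids, length(ids),
                                               replace = TRUE),
                                     simplify = FALSE))
  rows <- list()
  nConv <- 0L
  for (b in seq_len(n)) {
    pick <- draws[[b]]
    pieces <- lapply(seq_along(pick), function(k) {
      dd <- d[d$ID == pick[k], , drop = FALSE]
      dd$ID <- k
      dd
    })
    bstudy <- PKStudy(do.call(rbind, pieces), truth = list())
    bfit <- tryCatch(fitModel(bstudy, model, est, control),
                     error = function(e) NULL)
    if (!is.null(bfit) && bfit@converged) {
      nConv <- nConv + 1L
      rows[[length(rows) + 1L]] <- .paramVector(model, bfit@estimates)
    }
  }
  if (nConv == 0L) stop("no bootstrap resample converged")
  samples <- do.call(rbind, rows)
  med <- apply(samples, 2, median)
  lo <- apply(samples, 2, quantile, probs = 0.05)
  hi <- apply(samples, 2, quantile, probs = 0.95)
  flagged <- nConv < 0.8 * n
  if (flagged)
    warning(sprintf("bootstrap: only %d of %d resamples converged", nConv, n))
  new("BootstrapResult", median = med, ciLower = lo, ciUpper = hi,
      nResamples = as.integer(n), nConverged = nConv, flagged = flagged,
      samples = samples)
}

#' Table of estimates with bootstrap precision
#'
#' A report mirroring the conventional popPK parameter table: estimate,
#' RSE (%), bootstrap median and 90% CI per parameter.
#'
#' @param fit a [FitResult].
#' @param boot the matching [BootstrapResult].
#' @return a `data.frame` with one row per reported parameter.
#' @export
parameterTable <- function(fit, boot) {
  v <- .paramVector(fit@model, fit@estimates)
  rsev <- rep(NA_real_, length(v))
  names(rsev) <- names(v)
  shared <- intersect(names(fit@rse), names(v))
  rsev[shared] <- fit@rse[shared]
  data.frame(parameter = names(v), estimate = unname(v),
             rse_percent = unname(rsev),
             boot_median = unname(boot@median[names(v)]),
             ci5 = unname(boot@ciLower[names(v)]),
             ci95 = unname(boot@ciUpper[names(v)]),
             row.names = NULL)
}

## simulate one replicate observation vector for a subject under the model
.simulateSubject <- function(model, params, subj) {
  q <- length(model@iiv)
  eta <- if (q > 0) rnorm(q, 0, sqrt(as.numeric(params@omega2[model@iiv])))
         else numeric(0)
  f <- .predSubject(model, params, subj, eta)
  eps1 <- rnorm(subj$n, 0, sqrt(params@sigma2prop))
  eps2 <- if (params@sigma2add > 0) rnorm(subj$n, 0, sqrt(params@sigma2add))
          else 0
  residualMap(f, eps1, eps2)
}

#' Normalized prediction distribution errors (NPDE)
#'
#' For each subject, `nSim` replicate observation vectors are simulated
#' from the model; the observed and simulated vectors are decorrelated with
#' the empirical mean and Cholesky factor of the simulated covariance; the
#' prediction discrepancy of each observation is its rank among the
#' simulated values with a half-count continuity correction,
#' `pd = (#\{sim < obs\} + 0.5) / (nSim + 1)` (ties randomized under the
#' run's seed); and the npde is the standard-normal quantile of pd. Under a
#' correct model the npde are approximately N(0, 1).
#'
#' A simulated covariance with a zero-variance component (degenerate
#' simulations) is an error; a merely ill-conditioned one is repaired with
#' a 1e-8 diagonal ridge (with a message).
#'
#' @param study a [PKStudy].
#' @param model a [ModelSpec].
#' @param params a [ParameterSet] from a converged fit.
#' @param nSim number of simulated replicates (default 1000).
#' @param seed integer seed.
#' @return an [NpdeResult]; the summary tests are a t-test for mean zero, a
#'   chi-square test for unit variance, Shapiro-Wilk normality, and a
#'   Bonferroni global p-value.
#' @export
npdeEval <- function(study, model, params, nSim = 1000, seed) {
  subjects <- .subjectList(study, model)
  vals <- vector("list", length(subjects))
  for (i in seq_along(subjects)) {
    s <- subjects[[i]]
    if (s$n == 0) next
    ## per-subject stream keyed to the subject identity, so results do not
    ## depend on the order in which subjects appear
    vals[[i]] <- .withSeed(.subjectSeed(seed, s$id), {
      sims <- matrix(0, nSim, s$n)
      for (r in seq_len(nSim)) sims[r, ] <- .simulateSubject(model, params, s)
      m <- colMeans(sims)
      S <- stats::cov(sims)
      if (any(diag(S) <= 0))
        stop("singular simulated covariance for subject ", s$id,
             " (degenerate simulations)")
      L <- tryCatch(chol(S), error = function(e) NULL)
      if (is.null(L)) {
        message("npde: adding 1e-8 ridge to the simulated covariance of ",
                "subject ", s$id)
        L <- chol(S + diag(1e-8, s$n))
      }
      Lt <- t(L)
      yStar <- forwardsolve(Lt, s$y - m)
      simStar <- t(forwardsolve(Lt, t(sims) - m))
      pd <- numeric(s$n)
      for (j in seq_len(s$n)) {
        less <- sum(simStar[, j] < yStar[j])
        ties <- sum(simStar[, j] == yStar[j])
        if (ties > 0) less <- less + sample.int(ties + 1L, 1L) - 1L
        pd[j] <- (less + 0.5) / (nSim + 1)
      }
      qnorm(pd)
    })
  }
  npde <- unlist(vals)
  tests <- .npdeTests(npde)
  new("NpdeResult", values = npde, tests = tests, nSim = as.integer(nSim))
}

## deterministic per-subject seed below 2^31
.subjectSeed <- function(seed, id) {
  h <- 0
  for (ch in utf8ToInt(as.character(id))) h <- (h * 31 + ch) %% 1000003
  as.integer((seed %% 1000003) * 1009 + h) %% .Machine$integer.max
}

.npdeTests <- function(x) {
  n <- length(x)
  pMean <- t.test(x, mu = 0)$p.value
  stat <- (n - 1) * stats::var(x)  # ~ chi2(n-1) under unit variance
  pVar <- 2 * min(pchisq(stat, n - 1), 1 - pchisq(stat, n - 1))
  pNorm <- if (n >= 3 && n <= 5000) shapiro.test(x)$p.value else NA_real_
  pGlobal <- min(1, 3 * min(pMean, pVar, pNorm, na.rm = TRUE))
  data.frame(test = c("mean_zero", "unit_variance", "normality", "global"),
             statistic = c(mean(x), stats::var(x), NA, NA),
             p_value = c(pMean, pVar, pNorm, pGlobal))
}
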