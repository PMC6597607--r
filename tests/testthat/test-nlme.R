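# Marginal likelihood, estimation, empirical Bayes and residual
# diagnostics.

test_that("Laplace OFV agrees with adaptive Gauss-Hermite quadrature", {
  for (nEta in 1:2) {
    study <- toy_study(nEta)
    params <- toy_params(nEta)
    got <- marginalOFV(study, toy_model(nEta), params)
    want <- agq_study_ofv(study, params@thetas, params@omega2,
                          params@sigma2prop, ka = 1.5)
    expect_lt(abs(got - want), 0.1)
  }
})

test_that("OFV reduces to the closed-form normal likelihood without IIV", {
  study <- toy_study(1)
  model <- toy_model(1)
  params <- toy_params(1)
  params@omega2 <- c(cl = 0)
  d <- studyData(study)
  manual <- 0
  for (id in unique(d$ID)) {
    rows <- d[d$ID == id, ]
    obs <- rows[rows$EVID == 0, ]
    wt <- rows$WT[1]
    f <- conc1cmtOral(10, obs$TIME, 5 * (wt / 30)^0.75, 50 * (wt / 30), 1.5)
    v <- params@sigma2prop * f^2
    manual <- manual + sum(log(2 * pi * v) + (obs$DV - f)^2 / v)
  }
  expect_equal(marginalOFV(study, model, params), manual, tolerance = 1e-8)
})

test_that("OFV is additive over subjects", {
  study <- toy_study(1)
  d <- studyData(study)
  d2 <- d
  d2$ID <- d2$ID + 100
  doubled <- PKStudy(rbind(d, d2))
  m <- toy_model(1)
  p <- toy_params(1)
  expect_equal(marginalOFV(doubled, m, p), 2 * marginalOFV(study, m, p),
               tolerance = 1e-10)
})

test_that("OFV and etas are invariant to subject order", {
  study <- toy_study(2)
  d <- studyData(study)
  perm <- d[order(-d$ID, d$TIME), ]
  studyP <- PKStudy(perm)
  m <- toy_model(2)
  p <- toy_params(2)
  expect_equal(marginalOFV(studyP, m, p), marginalOFV(study, m, p),
               tolerance = 1e-10)
  e1 <- empiricalBayes(study, m, p)
  e2 <- empiricalBayes(studyP, m, p)
  expect_equal(e2[order(as.numeric(rownames(e2))), ],
               e1[order(as.numeric(rownames(e1))), ], tolerance = 1e-6)
})

test_that("empirical Bayes estimates are conditional modes", {
  study <- toy_study(1)
  m <- toy_model(1)
  p <- toy_params(1)
  etas <- empiricalBayes(study, m, p)
  # grid-search oracle over [-3 omega, 3 omega] on the joint density
  d <- studyData(study)
  for (id in 1:3) {
    rows <- d[d$ID == id, ]
    obs <- rows[rows$EVID == 0, ]
    wt <- rows$WT[1]
    g <- function(eta) {
      f <- conc1cmtOral(10, obs$TIME, 5 * (wt / 30)^0.75 * exp(eta),
                        50 * (wt / 30), 1.5)
      v <- 0.01 * f^2
      -sum(dnorm(obs$DV, f, sqrt(v), log = TRUE)) -
        dnorm(eta, 0, sqrt(0.1), log = TRUE)
    }
    grid <- seq(-3 * sqrt(0.1), 3 * sqrt(0.1), by = 1e-3)
    best <- grid[which.min(vapply(grid, g, numeric(1)))]
    expect_lt(abs(unname(etas[as.character(id), "cl"]) - best), 1e-3)
  }
  # shrinkage: omega2 -> 0 forces eta -> 0
  pSmall <- p
  pSmall@omega2 <- c(cl = 1e-10)
  expect_lt(max(abs(empiricalBayes(study, m, pSmall))), 1e-4)
  # a subject without observations sits at the prior mode
  d0 <- rbind(d, data.frame(ID = 99, TIME = 0, AMT = 10, EVID = 1, SS = 0,
                            II = 0, DV = NA, MDV = 1, WT = 25, AGE = 6,
                            SEX = 0))
  expect_equal(unname(empiricalBayes(PKStudy(d0), m, p, id = 99)), 0)
})

test_that("noise-free data identify the structural parameters", {
  # deterministic inverse problem: typical-value curves, variances pinned
  times <- c(0.5, 1, 2, 4, 8)
  rows <- lapply(1:8, function(i) {
    wt <- c(10, 15, 22, 30, 40, 55, 70, 80)[i]
    f <- conc1cmtOral(10, times, 5 * (wt / 30)^0.75, 50 * (wt / 30), 1.5)
    data.frame(ID = i, TIME = c(0, times), AMT = c(10, rep(0, 5)),
               EVID = c(1, rep(0, 5)), SS = 0, II = 0, DV = c(NA, f),
               MDV = c(1, rep(0, 5)), WT = wt, AGE = (wt - 8) / 2.8, SEX = 0)
  })
  study <- PKStudy(do.call(rbind, rows))
  init <- ParameterSet(c(cl = 8, cl_wt = 0.4, v = 30, v_wt = 1.4),
                       omega2 = c(cl = 1e-8), sigma2prop = 1e-6,
                       fixed = c("omega2.cl", "sigma2prop"))
  fit <- fitModel(study, toy_model(1), init)
  est <- estimates(fit)@thetas
  expect_equal(est[["cl"]], 5, tolerance = 1e-3)
  expect_equal(est[["cl_wt"]], 0.75, tolerance = 1e-3)
  expect_equal(est[["v"]], 50, tolerance = 1e-3)
  expect_equal(est[["v_wt"]], 1, tolerance = 1e-3)
})

test_that("refitting from the optimum is a fixed point", {
  study <- toy_study(1)
  fit1 <- fitModel(study, toy_model(1), toy_params(1))
  fit2 <- fitModel(study, toy_model(1), estimates(fit1))
  expect_true(fit1@converged)
  expect_lte(abs(ofv(fit2) - ofv(fit1)), 0.01)
})

test_that("CWRES are calibrated under the true model", {
  study <- simulateMidazolamStudy(7, n = 200)
  res <- cwres(study, midazolamModel(), midazolamTruth())
  expect_equal(nrow(res), nObservations(study))
  expect_gt(mean(res$CWRES), -0.1)
  expect_lt(mean(res$CWRES), 0.1)
  expect_gt(sd(res$CWRES), 0.85)
  expect_lt(sd(res$CWRES), 1.15)
})

test_that("CWRES vanish on noise-free data", {
  times <- c(0.5, 1, 2, 4, 8)
  rows <- lapply(1:3, function(i) {
    wt <- c(15, 30, 60)[i]
    f <- conc1cmtOral(10, times, 5 * (wt / 30)^0.75, 50 * (wt / 30), 1.5)
    data.frame(ID = i, TIME = c(0, times), AMT = c(10, rep(0, 5)),
               EVID = c(1, rep(0, 5)), SS = 0, II = 0, DV = c(NA, f),
               MDV = c(1, rep(0, 5)), WT = wt, AGE = (wt - 8) / 2.8, SEX = 0)
  })
  study <- PKStudy(do.call(rbind, rows))
  p <- toy_params(1)
  p@omega2 <- c(cl = 1e-8)
  res <- cwres(study, toy_model(1), p)
  expect_lt(max(abs(res$CWRES)), 1e-3)
})

test_that("RSEs are finite and plausibly sized on a midazolam-like fit", {
  study <- simulateMidazolamStudy(3)
  fit <- fitModel(study, midazolamModel(), midazolamTruth())
  r <- rse(fit)
  expect_true(all(is.finite(r[c("cl", "cl_wt")])))
  expect_lt(r[["cl"]], 60)
  expect_gt(r[["cl"]], 0.5)
})
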