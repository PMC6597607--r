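# Bootstrap and NPDE model evaluation.

test_that("bootstrap of a single-subject study is the identity resample", {
  d <- studyData(toy_study(1))
  one <- PKStudy(d[d$ID == 1, ])
  fit <- fitModel(one, toy_model(1), toy_params(1),
                  control = list(cycles = 1L))
  boot <- bootstrapFit(one, toy_model(1), fit, n = 1, seed = 5,
                       control = list(cycles = 1L))
  orig <- c(estimates(fit)@thetas,
            omega2.cl = estimates(fit)@omega2[["cl"]],
            sigma2prop = estimates(fit)@sigma2prop)
  expect_equal(boot@median[names(orig)], orig, tolerance = 1e-2)
  expect_equal(boot@nConverged, 1L)
})

test_that("bootstrap percentiles interpolate order statistics", {
  q <- quantile(1:100, c(0.05, 0.95), type = 7)
  expect_equal(unname(q), c(5.95, 95.05))
  # and the BootstrapResult CI uses exactly that convention
  study <- make_1cmt_study(11, n = 10, clExponent = 0.75)
  model <- toy_model(1)
  init <- toy_params(1)
  fit <- fitModel(study, model, init)
  boot <- bootstrapFit(study, model, fit, n = 12, seed = 2)
  expect_equal(unname(boot@ciLower["cl"]),
               unname(quantile(boot@samples[, "cl"], 0.05, type = 7)))
  expect_equal(unname(boot@ciUpper["cl"]),
               unname(quantile(boot@samples[, "cl"], 0.95, type = 7)))
  expect_true(all(boot@ciLower <= boot@median + 1e-12))
})

test_that("bootstrap intervals cover the generating parameters", {
  study <- make_1cmt_study(3, n = 40, clExponent = 0.75)
  model <- toy_model(1)
  fit <- fitModel(study, model, toy_params(1))
  boot <- bootstrapFit(study, model, fit, n = 50, seed = 9)
  truthv <- c(cl = 5, cl_wt = 0.75, v = 50, v_wt = 1, omega2.cl = 0.05,
              sigma2prop = 0.02)
  inside <- sum(truthv >= boot@ciLower[names(truthv)] &
                  truthv <= boot@ciUpper[names(truthv)])
  expect_gte(inside, 5)  # at least 5 of the 6 estimated quantities
  expect_s4_class(boot, "BootstrapResult")
  expect_lte(boot@nConverged, boot@nResamples)
})

test_that("bootstrap is reproducible for a fixed seed", {
  study <- make_1cmt_study(4, n = 8, clExponent = 0.75)
  fit <- fitModel(study, toy_model(1), toy_params(1))
  b1 <- bootstrapFit(study, toy_model(1), fit, n = 5, seed = 31)
  b2 <- bootstrapFit(study, toy_model(1), fit, n = 5, seed = 31)
  expect_identical(b1@samples, b2@samples)
})

test_that("npde values are near-N(0,1) under the true model", {
  study <- simulateMidazolamStudy(21)
  res <- npdeEval(study, midazolamModel(), midazolamTruth(), nSim = 200,
                  seed = 1)
  x <- npdeValues(res)
  expect_length(x, nObservations(study))
  expect_lt(abs(mean(x)), 0.25)
  expect_lt(abs(sd(x) - 1), 0.25)
  ks <- suppressWarnings(ks.test(x, "pnorm"))
  expect_gt(ks$p.value, 0.01)
})

test_that("npde is reproducible and permutation invariant", {
  study <- simulateSildenafilStudy(5, n = 40, groupSizes = c(10, 14, 16))
  m <- sildenafilModel()
  p <- sildenafilTruth()
  r1 <- npdeEval(study, m, p, nSim = 100, seed = 8)
  r2 <- npdeEval(study, m, p, nSim = 100, seed = 8)
  expect_identical(npdeValues(r1), npdeValues(r2))
  # same subjects presented in reverse order: same per-subject values
  d <- studyData(study)
  perm <- do.call(rbind, lapply(rev(unique(d$ID)), function(i)
    d[d$ID == i, ]))
  r3 <- npdeEval(PKStudy(perm), m, p, nSim = 100, seed = 8)
  expect_equal(sort(npdeValues(r3)), sort(npdeValues(r1)), tolerance = 1e-9)
})

test_that("degenerate simulations raise the singular-covariance error", {
  # zero residual and IIV variance: all replicates identical
  d <- studyData(toy_study(1))
  study <- PKStudy(d[d$ID == 1, ])
  p <- toy_params(1)
  p@omega2 <- c(cl = 0)
  p@sigma2prop <- 0
  expect_error(npdeEval(study, toy_model(1), p, nSim = 30, seed = 2),
               "singular")
})

test_that("parameterTable lines up estimates with bootstrap columns", {
  study <- make_1cmt_study(6, n = 8, clExponent = 0.75)
  fit <- fitModel(study, toy_model(1), toy_params(1))
  boot <- bootstrapFit(study, toy_model(1), fit, n = 4, seed = 3)
  tab <- parameterTable(fit, boot)
  expect_setequal(tab$parameter,
                  c("cl", "cl_wt", "v", "v_wt", "omega2.cl", "sigma2prop"))
  expect_equal(tab$estimate[tab$parameter == "cl"],
               estimates(fit)@thetas[["cl"]])
})
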