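# Structural model layer: analytical solutions, covariate machinery,
# residual mapping.

test_that("predictions vanish at t = 0 and scale linearly in dose", {
  p2 <- list(cl = 102.6, vc = 156, q = 121.8, vp = 255)
  expect_equal(conc2cmtOral(12.5, 0, p2$cl, p2$vc, p2$q, p2$vp, 3.5), 0)
  expect_equal(conc1cmtOral(10, 0, 5, 50, 1.5), 0)
  tt <- c(0.25, 0.5, 1, 2, 4, 8, 22)
  c1 <- conc2cmtOral(5, tt, p2$cl, p2$vc, p2$q, p2$vp, 3.5)
  c2 <- conc2cmtOral(10, tt, p2$cl, p2$vc, p2$q, p2$vp, 3.5)
  expect_equal(c2, 2 * c1, tolerance = 1e-12)
  expect_true(all(c1 >= 0))
  expect_true(conc2cmtOral(12.5, 1e4, p2$cl, p2$vc, p2$q, p2$vp, 3.5) < 1e-10)
})

test_that("two-compartment analytical solution matches an ODE oracle", {
  skip_if_not_installed("deSolve")
  p <- list(cl = 102.6, vc = 156, q = 121.8, vp = 255, ka = 3.5)
  dose <- 12.5
  rhs <- function(t, x, parms) {
    with(parms, {
      dA <- -ka * x[1]
      dC <- ka * x[1] - (cl / vc) * x[2] - (q / vc) * x[2] + (q / vp) * x[3]
      dP <- (q / vc) * x[2] - (q / vp) * x[3]
      list(c(dA, dC, dP))
    })
  }
  tt <- seq(0.25, 22, length.out = 100)
  sol <- deSolve::lsoda(c(dose, 0, 0), c(0, tt), rhs, parms = p,
                        rtol = 1e-10, atol = 1e-12)
  odeConc <- sol[-1, 3] / p$vc
  ana <- conc2cmtOral(dose, tt, p$cl, p$vc, p$q, p$vp, p$ka)
  expect_equal(ana, unname(odeConc), tolerance = 1e-6)
})

test_that("two-compartment model nests the one-compartment solution", {
  tt <- c(0.5, 1, 2, 4, 8, 22)
  lim <- conc2cmtOral(12.5, tt, 102.6, 156, 1e-9, 1e-9, 3.5)
  one <- conc1cmtOral(12.5, tt, 102.6, 156, 3.5)
  expect_equal(lim, one, tolerance = 1e-6)
  # exact-zero path
  expect_equal(conc2cmtOral(12.5, tt, 102.6, 156, 0, 0, 3.5), one,
               tolerance = 1e-12)
})

test_that("coincident rates are handled without NaN", {
  # ka equal to the elimination rate constant
  v <- conc1cmtOral(10, c(0.5, 2, 8), cl = 75, v = 50, ka = 1.5)
  expect_true(all(is.finite(v) & v >= 0))
  vss <- conc1cmtOralSS(10, 8, c(0, 3, 8), cl = 75, v = 50, ka = 1.5)
  expect_true(all(is.finite(vss) & vss >= 0))
})

test_that("single oral dose mass balance holds on the apparent scale", {
  # integral of CL * C(t) over (0, Inf) returns the dose
  p <- list(cl = 102.6, vc = 156, q = 121.8, vp = 255, ka = 3.5)
  el2 <- integrate(function(t) p$cl * conc2cmtOral(12.5, t, p$cl, p$vc,
                                                   p$q, p$vp, p$ka),
                   0, Inf, rel.tol = 1e-9)$value
  expect_equal(el2, 12.5, tolerance = 1e-3)
  el1 <- integrate(function(t) 5 * conc1cmtOral(10, t, 5, 50, 1.5),
                   0, Inf, rel.tol = 1e-9)$value
  expect_equal(el1, 10, tolerance = 1e-3)
})

test_that("steady-state solution is periodic and matches superposition", {
  p <- list(cl = 113, v = 540, ka = 1)
  expect_equal(conc1cmtOralSS(20, 8, 0, p$cl, p$v, p$ka),
               conc1cmtOralSS(20, 8, 8, p$cl, p$v, p$ka), tolerance = 1e-12)
  for (t in c(0, 3, 6, 8)) {
    sup <- oracle_conc1_ss(20, 8, t, p$cl, p$v, p$ka, nDoses = 200)
    expect_equal(conc1cmtOralSS(20, 8, t, p$cl, p$v, p$ka), sup,
                 tolerance = 1e-8)
  }
  # an effectively infinite interval recovers the single-dose curve
  expect_equal(conc1cmtOralSS(20, 1e4, 3, p$cl, p$v, p$ka),
               conc1cmtOral(20, 3, p$cl, p$v, p$ka), tolerance = 1e-8)
  expect_error(conc1cmtOralSS(20, 8, 9, p$cl, p$v, p$ka), "within")
})

test_that("individualParam implements the power covariate model", {
  # covariate at its reference with eta = 0 returns the typical value
  wt30 <- covTerm("cl", "weight", 30.2, fixed = 0.874)
  expect_equal(individualParam(102.6, list(wt30), list(weight = 30.2)), 102.6)
  # no terms: identity
  expect_equal(individualParam(7.3, list(), list(weight = 1)), 7.3)
  # the adult-to-child worked example: 100 L/h at 70 kg scaled to 28 kg
  wt70 <- covTerm("cl", "weight", 70, fixed = 0.874)
  expect_equal(signif(individualParam(100, list(wt70), list(weight = 28)), 3),
               44.9)
  # eta acts multiplicatively on the log-normal scale
  expect_equal(individualParam(100, list(), list(), eta = log(2)), 200)
  expect_error(individualParam(100, list(wt70), list(age = 3)), "missing")
})

test_that("residualMap combines proportional and additive errors", {
  expect_equal(residualMap(10, 0, 0), 10)
  expect_equal(residualMap(10, 0.1, 0), 11)
  expect_equal(residualMap(10, 0.1, 0.5), 11.5)
  expect_equal(residualMap(c(10, 20), c(0.1, -0.5), 1), c(12, 11))
})
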