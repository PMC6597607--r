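# Clearance scaling, prediction error, accuracy criteria.

test_that("scaleClearance evaluates the allometric function", {
  sf <- ScalingFunction(clRef = 100)
  expect_equal(scaleClearance(sf, 70), 100)
  expect_equal(signif(scaleClearance(sf, 28), 3), 44.9)
  expect_equal(signif(scaleClearance(sf, 10), 4), 18.26)
  # homogeneity in the reference clearance
  expect_equal(scaleClearance(ScalingFunction(300), c(10, 28, 50)),
               3 * scaleClearance(sf, c(10, 28, 50)))
  # strictly increasing in weight for a positive exponent
  w <- seq(5, 100, by = 5)
  expect_true(all(diff(scaleClearance(sf, w)) > 0))
  expect_error(scaleClearance(sf, -1), "> 0")
})

test_that("re-referencing the sparse-study model reproduces its child value", {
  ref <- ScalingFunction(113, wtRef = 70, exponent = 1.08)
  expect_equal(scaleClearance(ref, 28), 41.9, tolerance = 0.005 * 41.9)
})

test_that("prediction error is the signed relative deviation in percent", {
  expect_equal(predictionError(50, 50), 0)
  expect_equal(predictionError(75, 100), -25)
  sc <- scaleClearance(ScalingFunction(100), c(50, 20, 10))
  rf <- scaleClearance(ScalingFunction(113, 70, 1.08), c(50, 20, 10))
  expect_equal(round(predictionError(sc, rf), 1), c(-5.2, 14.5, 32.1),
               tolerance = 0.2)
  expect_error(predictionError(10, 0), "> 0")
})

test_that("accuracy classes follow the 30/50 percent thresholds", {
  expect_equal(as.character(classifyAccuracy(-5.2)), "accurate")
  expect_equal(as.character(classifyAccuracy(-44.6)), "reasonably_accurate")
  expect_equal(as.character(classifyAccuracy(-64.3)), "inaccurate")
  expect_equal(as.character(classifyAccuracy(c(29.999, 30, 49.999, 50))),
               c("accurate", "reasonably_accurate", "reasonably_accurate",
                 "inaccurate"))
  # class is monotone in |PE|
  pes <- seq(-80, 80, by = 2.5)
  lev <- as.integer(classifyAccuracy(pes))
  expect_true(all(diff(lev[pes >= 0]) >= 0))
  expect_true(all(diff(lev[pes <= 0]) <= 0))
  expect_error(classifyAccuracy(NaN), "finite")
})

test_that("cvPercent converts a log-scale variance", {
  expect_equal(cvPercent(0.16), 100 * sqrt(exp(0.16) - 1))
  expect_equal(cvPercent(0), 0)
  expect_equal(cvPercent(log(2)), 100)
  expect_error(cvPercent(-0.1), ">= 0")
})

test_that("apparentClearance divides by bioavailability", {
  expect_equal(apparentClearance(41, 0.41), 100)
  expect_equal(apparentClearance(7, 1), 7)
  expect_equal(apparentClearance(20, 0.5), 40)
  expect_error(apparentClearance(10, 0), "bioavailability")
  expect_error(apparentClearance(10, 1.2), "bioavailability")
})

test_that("the neonatal criteria gate on protein, binding and extraction", {
  hsa <- function(fu, er) minAccurateAge(
    DrugProperties("x", er, fu, "HSA", 0.9))@minAgeClass
  aag <- function(fu, er) minAccurateAge(
    DrugProperties("x", er, fu, "AAG", 0.9))@minAgeClass
  expect_equal(hsa(0.05, 0.30), "1 day")
  expect_equal(hsa(0.05, 0.60), "indeterminate")  # above 0.55 at high binding
  expect_equal(hsa(0.9, 0.70), "indeterminate")   # above 0.65 at low binding
  expect_equal(hsa(0.9, 0.50), "1 day")
  # interpolation midpoint: fu = 0.5 gives a 0.20-0.60 window
  expect_equal(hsa(0.5, 0.21), "1 day")
  expect_equal(hsa(0.5, 0.18), "indeterminate")
  expect_equal(aag(0.50, 0.50), "indeterminate")  # no accurate AAG scenario
  expect_equal(aag(0.02, 0.30), "1 day")
  expect_equal(aag(0.09, 0.45), "1 day")
  expect_equal(aag(0.02, 0.05), "indeterminate")
})

test_that("low CYP3A fraction yields an indeterminate verdict", {
  props <- DrugProperties("x", 0.3, 0.05, "HSA", fCyp3a = 0.5)
  expect_warning(v <- minAccurateAge(props), "75")
  expect_equal(v@minAgeClass, "indeterminate")
})

test_that("a lookup grid assigns the finer age classes", {
  grid <- data.frame(protein = "HSA", fu_min = 0, fu_max = 1,
                     er_min = 0.8, er_max = 1, age_class = "6 months")
  props <- DrugProperties("x", 0.85, 0.05, "HSA", 0.9)
  v <- minAccurateAge(props, grid)
  expect_equal(v@minAgeClass, "6 months")
  expect_equal(v@basis, "lookup_table")
  # malformed grids are configuration errors
  expect_error(minAccurateAge(props, data.frame(protein = "HSA")),
               "malformed")
  bad <- grid
  bad$age_class <- "sometime"
  expect_error(minAccurateAge(props, bad), "unknown age class")
  # without a grid only 1 day / indeterminate are reachable
  set.seed(1)
  classes <- replicate(60, minAccurateAge(
    DrugProperties("x", runif(1, 0.01, 0.99), runif(1, 0.01, 1),
                   sample(c("HSA", "AAG"), 1), 0.9))@minAgeClass)
  expect_true(all(classes %in% c("1 day", "indeterminate")))
})

test_that("the PE report reproduces hand arithmetic to 0.1 points", {
  drugs <- data.frame(name = c("drugA", "drugB"),
                      cl_adult = c(100, 40),
                      ref_cl = c(113, 50), ref_wt = c(70, 70),
                      ref_exp = c(1.08, 0.75))
  rep <- peReport(drugs)
  expect_equal(nrow(rep), 6)
  hand <- (100 * (20 / 70)^0.874 - 113 * (20 / 70)^1.08) /
    (113 * (20 / 70)^1.08) * 100
  got <- rep$pe[rep$name == "drugA" & rep$weight == 20]
  expect_lt(abs(got - hand), 0.1)
  # identical scaled and reference functions give all-zero accurate rows
  same <- data.frame(name = "self", cl_adult = 100, ref_cl = 100,
                     ref_wt = 70, ref_exp = 0.874)
  repSame <- peReport(same)
  expect_true(all(repSame$pe == 0))
  expect_true(all(repSame$accuracy == "accurate"))
})

test_that("the shipped minimum-age reference table is consistent", {
  tab <- cyp3aMinAgeReference()
  expect_true(all(c("name", "min_age_class") %in% names(tab)))
  expect_true("sildenafil" %in% tab$name)
  expect_true(all(tab$min_age_class %in% c(
    "1 day", "1 month", "6 months", "1 year", "2 years", "5 years",
    "not_accurate_le_5y", "indeterminate")))
})
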