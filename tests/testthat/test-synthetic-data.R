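# Study simulators.

test_that("simulated studies are bit-identical for a fixed seed", {
  a <- simulateMidazolamStudy(17)
  b <- simulateMidazolamStudy(17)
  expect_identical(studyData(a), studyData(b))
  expect_identical(studyTruth(a), studyTruth(b))
  s1 <- simulateSildenafilStudy(17)
  s2 <- simulateSildenafilStudy(17)
  expect_identical(studyData(s1), studyData(s2))
  # simulators do not disturb the caller's RNG stream
  set.seed(99)
  before <- runif(1)
  set.seed(99)
  invisible(simulateMidazolamStudy(3))
  expect_identical(runif(1), before)
})

test_that("the dense design matches its published envelope", {
  study <- simulateMidazolamStudy(2)
  d <- studyData(study)
  expect_equal(nSubjects(study), 31)
  first <- !duplicated(d$ID)
  expect_true(all(d$WT >= 9.5 & d$WT <= 83.2))
  expect_true(all(d$AGE >= 1 & d$AGE <= 17))
  doses <- d$AMT[d$EVID == 1]
  expect_true(all(doses >= 3 & doses <= 15))
  perSubj <- table(d$ID[d$EVID == 0])
  expect_true(all(perSubj >= 8 & perSubj <= 11))
  expect_true(median(perSubj) >= 8 && median(perSubj) <= 11)
  # one dose per subject at time zero
  dose <- d[d$EVID == 1, ]
  expect_equal(nrow(dose), 31)
  expect_true(all(dose$TIME == 0))
})

test_that("zero variability reproduces the typical-value predictions", {
  tr <- midazolamTruth()
  tr@omega2 <- c(cl = 0, vc = 0)
  tr@sigma2prop <- 0
  study <- simulateMidazolamStudy(5, truth = tr)
  d <- studyData(study)
  obs <- d[d$EVID == 0, ]
  for (id in unique(obs$ID)[1:5]) {
    rows <- obs[obs$ID == id, ]
    wt <- rows$WT[1]
    dose <- d$AMT[d$ID == id & d$EVID == 1]
    f <- conc2cmtOral(dose, rows$TIME,
                      102.6 * (wt / 30.2)^0.874, 156 * (wt / 30.2)^1.88,
                      121.8 * (wt / 30.2)^0.75, 255 * (wt / 30.2)^0.91, 3.5)
    expect_equal(rows$DV, f, tolerance = 1e-12)
  }
})

test_that("the sparse design honors the weight-stratified dosing rule", {
  study <- simulateSildenafilStudy(13)
  d <- studyData(study)
  expect_equal(nSubjects(study), 156)
  dose <- d[d$EVID == 1, ]
  expect_true(all(dose$SS == 1 & dose$II == 8))
  # allowed dose by weight stratum (low 10 only above 20 kg)
  light <- dose$WT <= 20
  expect_true(all(dose$AMT[light] %in% c(10, 20)))      # medium 10 / high 20
  mid <- dose$WT > 20 & dose$WT <= 45
  expect_true(all(dose$AMT[mid] %in% c(10, 20, 40)))
  heavy <- dose$WT > 45
  expect_true(all(dose$AMT[heavy] %in% c(10, 40, 80)))
  # group sizes are preserved by the swap repair
  expect_equal(sort(unname(unlist(studyTruth(study)$groups))),
               sort(c(39, 48, 69)))
  perSubj <- table(d$ID[d$EVID == 0])
  expect_true(all(perSubj >= 1 & perSubj <= 4))
  obs <- d[d$EVID == 0, ]
  expect_true(all(obs$TIME >= 0 & obs$TIME <= 8))
})

test_that("group sizes are configurable", {
  study <- simulateSildenafilStudy(1, n = 30, groupSizes = c(8, 10, 12))
  expect_equal(sort(unname(unlist(studyTruth(study)$groups))),
               sort(c(8, 10, 12)))
})

test_that("additive-error negatives are truncated and flagged", {
  tr <- midazolamTruth()
  tr@sigma2add <- 25  # exaggerated additive noise to force negatives
  mdl <- midazolamModel()
  mdl@errorModel <- "combined"
  study <- simulateMidazolamStudy(8, truth = tr, model = mdl)
  d <- studyData(study)
  expect_true(all(d$DV[d$EVID == 0] >= 0))
  expect_gt(studyTruth(study)$truncated_negative, 0)
})

test_that("datasets round-trip through the writer and reader", {
  study <- simulateSildenafilStudy(3, n = 20, groupSizes = c(5, 7, 8))
  csv <- tempfile(fileext = ".csv")
  yml <- tempfile(fileext = ".yaml")
  writeDataset(study, csv, truthPath = yml)
  back <- readDataset(csv)
  expect_equal(studyData(back), studyData(study), tolerance = 1e-12)
  tr <- yaml::read_yaml(yml)
  expect_equal(tr$thetas$cl, 113)
  unlink(c(csv, yml))
})
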