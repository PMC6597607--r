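# Shared fixtures: the shipped 3-subject toys and a small configurable
# 1-compartment study generator used by the selection/bootstrap tests.

toy_model <- function(nEta = 1) {
  ModelSpec(1, ka = 1.5, dosing = "single",
            iiv = if (nEta == 2) c("cl", "v") else "cl",
            covariates = list(covTerm("cl", "weight", 30, theta = "cl_wt"),
                              covTerm("v", "weight", 30, theta = "v_wt")))
}

toy_params <- function(nEta = 1) {
  ParameterSet(c(cl = 5, cl_wt = 0.75, v = 50, v_wt = 1),
               omega2 = if (nEta == 2) c(cl = 0.1, v = 0.09) else c(cl = 0.1),
               sigma2prop = 0.01)
}

toy_study <- function(nEta = 1) {
  file <- if (nEta == 2) "toy_1cmt_2eta.csv" else "toy_1cmt_1eta.csv"
  readDataset(system.file("extdata", file, package = "pedpk"))
}

# simple dense 1-compartment study with a weight effect on clearance of
# chosen size (exponent), optional sex effect, for selection experiments
make_1cmt_study <- function(seed, n = 16, clExponent = 0, sexFraction = 1,
                            omega2cl = 0.05, sigma2 = 0.02,
                            times = c(0.5, 1, 2, 4, 8)) {
  withr::with_seed(seed, {
    wt <- exp(runif(n, log(10), log(80)))
    age <- pmin(17, pmax(1, (wt - 8) / 2.8 * exp(rnorm(n, 0, 0.25))))
    sex <- rbinom(n, 1, 0.5)
    rows <- lapply(seq_len(n), function(i) {
      cl <- 5 * (wt[i] / 30)^clExponent *
        (if (sex[i] == 1) sexFraction else 1) * exp(rnorm(1, 0, sqrt(omega2cl)))
      v <- 50 * (wt[i] / 30)
      f <- conc1cmtOral(10, times, cl, v, 1.5)
      y <- residualMap(f, rnorm(length(times), 0, sqrt(sigma2)))
      data.frame(ID = i, TIME = c(0, times), AMT = c(10, rep(0, length(times))),
                 EVID = c(1, rep(0, length(times))), SS = 0, II = 0,
                 DV = c(NA, y), MDV = c(1, rep(0, length(times))),
                 WT = wt[i], AGE = age[i], SEX = sex[i])
    })
    PKStudy(do.call(rbind, rows))
  })
}

# base model/init matching make_1cmt_study without any covariates
base_1cmt_model <- function() {
  ModelSpec(1, ka = 1.5, dosing = "single", iiv = "cl",
            covariates = list(covTerm("v", "weight", 30, fixed = 1)))
}

base_1cmt_init <- function() {
  ParameterSet(c(cl = 5, v = 50), omega2 = c(cl = 0.05), sigma2prop = 0.02)
}
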