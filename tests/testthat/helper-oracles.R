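# Independent oracles, written against plain-R model formulas (not the
# package's computation path), used to arbitrate the analytical solutions
# and the Laplace marginal likelihood.

# one-compartment oral concentration, plain R
oracle_conc1 <- function(dose, t, cl, v, ka) {
  ke <- cl / v
  ifelse(t <= 0, 0,
         dose * ka / (v * (ka - ke)) * (exp(-ke * t) - exp(-ka * t)))
}

# steady-state by truncated superposition over past doses
oracle_conc1_ss <- function(dose, tau, tAfter, cl, v, ka, nDoses = 200) {
  out <- 0
  for (k in 0:(nDoses - 1)) out <- out + oracle_conc1(dose, tAfter + k * tau,
                                                      cl, v, ka)
  out
}

# Gauss-Hermite nodes/weights by Golub-Welsch (physicists' convention:
# integral of f(x) exp(-x^2) dx = sum w_i f(x_i))
gh_rule <- function(n) {
  J <- matrix(0, n, n)
  for (i in seq_len(n - 1)) J[i, i + 1] <- J[i + 1, i] <- sqrt(i / 2)
  e <- eigen(J, symmetric = TRUE)
  idx <- order(e$values)
  list(x = e$values[idx], w = sqrt(pi) * e$vectors[1, idx]^2)
}

# adaptive Gauss-Hermite -2 log marginal likelihood for a 1-compartment
# single-dose toy subject with log-normal random effects on (cl[, v])
agq_subject_ofv <- function(y, times, dose, cl, v, ka, omega2, s2p,
                            s2a = 0, nNodes = 21) {
  q <- length(omega2)
  loglik_cond <- function(eta) {
    cli <- cl * exp(eta[1])
    vi <- v * exp(if (q > 1) eta[2] else 0)
    f <- oracle_conc1(dose, times, cli, vi, ka)
    vv <- s2p * f^2 + s2a
    sum(dnorm(y, f, sqrt(vv), log = TRUE))
  }
  g <- function(eta) -(loglik_cond(eta) +
                         sum(dnorm(eta, 0, sqrt(omega2), log = TRUE)))
  if (q == 1) {
    opt <- optimize(function(e) g(e), c(-5, 5))
    m <- opt$minimum
    h <- 1e-4
    hess <- (g(m + h) - 2 * g(m) + g(m - h)) / h^2
    s <- 1 / sqrt(hess)
    r <- gh_rule(nNodes)
    vals <- vapply(seq_along(r$x), function(k) {
      e <- m + sqrt(2) * s * r$x[k]
      r$w[k] * exp(r$x[k]^2) * exp(-g(e))
    }, numeric(1))
    -2 * log(sqrt(2) * s * sum(vals))
  } else {
    opt <- optim(c(0, 0), g, method = "BFGS")
    m <- opt$par
    h <- 1e-4
    H <- matrix(0, 2, 2)
    for (i in 1:2) {
      ei <- rep(0, 2); ei[i] <- h
      H[i, i] <- (g(m + ei) - 2 * g(m) + g(m - ei)) / h^2
    }
    e12 <- c(h, h)
    H[1, 2] <- H[2, 1] <-
      (g(m + e12) - g(m + c(h, -h)) - g(m + c(-h, h)) + g(m - e12)) /
      (4 * h^2)
    A <- t(chol(solve(H)))
    r <- gh_rule(nNodes)
    total <- 0
    for (j in seq_along(r$x)) for (k in seq_along(r$x)) {
      x <- c(r$x[j], r$x[k])
      e <- m + sqrt(2) * as.numeric(A %*% x)
      total <- total + r$w[j] * r$w[k] * exp(sum(x^2)) * exp(-g(e))
    }
    -2 * log(2 * abs(det(A)) * total)
  }
}

# AGQ OFV for a whole 1-compartment toy study expressed as a PKStudy whose
# model has weight-power covariates on cl (exponent thetas$cl_wt) and v
agq_study_ofv <- function(study, thetas, omega2, s2p, ka, nNodes = 21) {
  d <- pedpk::studyData(study)
  total <- 0
  for (id in unique(d$ID)) {
    rows <- d[d$ID == id, ]
    obs <- rows[rows$EVID == 0, ]
    dose <- rows$AMT[rows$EVID == 1][1]
    wt <- rows$WT[1]
    cl <- thetas[["cl"]] * (wt / 30)^thetas[["cl_wt"]]
    v <- thetas[["v"]] * (wt / 30)^thetas[["v_wt"]]
    total <- total + agq_subject_ofv(obs$DV, obs$TIME, dose, cl, v, ka,
                                     omega2, s2p, nNodes = nNodes)
  }
  total
}
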