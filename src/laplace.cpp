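#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Analytical oral-absorption solutions. All parameters are apparent (CL/F
// scale); concentrations in mg/L; times in h. A relative perturbation of
// 1e-8 separates coincident exponential rates so the macro-constant forms
// never divide by zero.

static const double RATE_TOL = 1e-8;

static inline void separate(double &a, double &b) {
  // nudge b away from a when the two rates (nearly) coincide
  double scale = std::max(std::abs(a), std::abs(b));
  if (std::abs(a - b) < RATE_TOL * scale) b = a * (1.0 + RATE_TOL * 2.0);
}

static double conc1_single(double dose, double t, double cl, double v, double ka) {
  if (t <= 0.0) return 0.0;
  double ke = cl / v;
  double ka_ = ka;
  separate(ke, ka_);
  double c = dose * ka_ / (v * (ka_ - ke)) * (std::exp(-ke * t) - std::exp(-ka_ * t));
  return c > 0.0 ? c : 0.0;
}

static double conc1_ss(double dose, double tau, double t, double cl, double v, double ka) {
  double ke = cl / v;
  double ka_ = ka;
  separate(ke, ka_);
  double eke = std::exp(-ke * tau), eka = std::exp(-ka_ * tau);
  double c = dose * ka_ / (v * (ka_ - ke)) *
    (std::exp(-ke * t) / (1.0 - eke) - std::exp(-ka_ * t) / (1.0 - eka));
  return c > 0.0 ? c : 0.0;
}

static double conc2_single(double dose, double t, double cl, double vc,
                           double q, double vp, double ka) {
  if (t <= 0.0) return 0.0;
  if (q < 1e-12 || vp < 1e-12) return conc1_single(dose, t, cl, vc, ka);
  double k10 = cl / vc, k12 = q / vc, k21 = q / vp;
  double s = k10 + k12 + k21;
  double disc = s * s - 4.0 * k10 * k21;
  disc = disc > 0.0 ? std::sqrt(disc) : 0.0;
  double alpha = 0.5 * (s + disc);
  double beta  = 0.5 * (s - disc);
  separate(alpha, beta);
  double ka_ = ka;
  separate(alpha, ka_);
  separate(beta, ka_);
  double A = (k21 - alpha) / ((ka_ - alpha) * (beta - alpha));
  double B = (k21 - beta)  / ((ka_ - beta)  * (alpha - beta));
  double C = (k21 - ka_)   / ((alpha - ka_) * (beta - ka_));
  double c = dose * ka_ / vc *
    (A * std::exp(-alpha * t) + B * std::exp(-beta * t) + C * std::exp(-ka_ * t));
  return c > 0.0 ? c : 0.0;
}

// [[Rcpp::export]]
NumericVector cpp_conc2cmt(double dose, NumericVector t, double cl, double vc,
                           double q, double vp, double ka) {
  int n = t.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = conc2_single(dose, t[i], cl, vc, q, vp, ka);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_conc1cmt(double dose, NumericVector t, double cl, double v, double ka) {
  int n = t.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = conc1_single(dose, t[i], cl, v, ka);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_conc1cmt_ss(double dose, double tau, NumericVector t,
                              double cl, double v, double ka) {
  int n = t.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = conc1_ss(dose, tau, t[i], cl, v, ka);
  return out;
}

// ---------------------------------------------------------------------------
// Per-subject joint negative log density and its Laplace-approximated
// marginal. model: 1 = two-compartment single oral dose, 2 = one-compartment
// steady-state oral dosing, 3 = one-compartment single oral dose.
// ptyp holds the subject's covariate-adjusted typical structural parameters
// (model 1: cl, vc, q, vp; models 2/3: cl, v); etaMap gives for each
// structural parameter the 0-based index of its random effect or -1.

struct SubjData {
  NumericVector t, y;
  double dose, tau, ka, s2p, s2a;
  int model;
  NumericVector ptyp;
  IntegerVector etaMap;
  NumericVector omega2;
};

// g(eta) = -log p(y, eta) up to nothing omitted (full 2*pi constants)
static double gfun(const SubjData &d, const std::vector<double> &eta) {
  const double LOG2PI = 1.8378770664093453;
  int np = d.ptyp.size();
  std::vector<double> p(np);
  for (int j = 0; j < np; ++j) {
    double e = (d.etaMap[j] >= 0) ? eta[d.etaMap[j]] : 0.0;
    p[j] = d.ptyp[j] * std::exp(e);
  }
  double val = 0.0;
  int n = d.t.size();
  for (int i = 0; i < n; ++i) {
    double f;
    if (d.model == 1)      f = conc2_single(d.dose, d.t[i], p[0], p[1], p[2], p[3], d.ka);
    else if (d.model == 2) f = conc1_ss(d.dose, d.tau, d.t[i], p[0], p[1], d.ka);
    else                   f = conc1_single(d.dose, d.t[i], p[0], p[1], d.ka);
    double v = d.s2p * f * f + d.s2a;
    if (v < 1e-10) v = 1e-10;
    double r = d.y[i] - f;
    val += 0.5 * (LOG2PI + std::log(v) + r * r / v);
  }
  int q = d.omega2.size();
  for (int k = 0; k < q; ++k) {
    double w = d.omega2[k] < 1e-12 ? 1e-12 : d.omega2[k];
    val += 0.5 * (LOG2PI + std::log(w) + eta[k] * eta[k] / w);
  }
  return val;
}

static void predvec(const SubjData &d, const std::vector<double> &eta,
                    std::vector<double> &f) {
  int np = d.ptyp.size();
  std::vector<double> p(np);
  for (int j = 0; j < np; ++j) {
    double e = (d.etaMap[j] >= 0) ? eta[d.etaMap[j]] : 0.0;
    p[j] = d.ptyp[j] * std::exp(e);
  }
  int n = d.t.size();
  f.resize(n);
  for (int i = 0; i < n; ++i) {
    if (d.model == 1)      f[i] = conc2_single(d.dose, d.t[i], p[0], p[1], p[2], p[3], d.ka);
    else if (d.model == 2) f[i] = conc1_ss(d.dose, d.tau, d.t[i], p[0], p[1], d.ka);
    else                   f[i] = conc1_single(d.dose, d.t[i], p[0], p[1], d.ka);
  }
}

// gradient of g by central differences
static void grad_fd(const SubjData &d, const std::vector<double> &eta,
                    std::vector<double> &g) {
  int q = eta.size();
  double h = 1e-5;
  std::vector<double> e(eta);
  for (int k = 0; k < q; ++k) {
    e[k] = eta[k] + h; double fp = gfun(d, e);
    e[k] = eta[k] - h; double fm = gfun(d, e);
    e[k] = eta[k];
    g[k] = (fp - fm) / (2.0 * h);
  }
}

// exact Hessian of g by central differences
static void hess_fd(const SubjData &d, const std::vector<double> &eta,
                    std::vector<double> &H) {
  int q = eta.size();
  double h = 1e-4;
  double f0 = gfun(d, eta);
  std::vector<double> e(eta);
  for (int k = 0; k < q; ++k) {
    e[k] = eta[k] + h; double fp = gfun(d, e);
    e[k] = eta[k] - h; double fm = gfun(d, e);
    e[k] = eta[k];
    H[k * q + k] = (fp - 2.0 * f0 + fm) / (h * h);
  }
  for (int k = 0; k < q; ++k)
    for (int l = k + 1; l < q; ++l) {
      e[k] += h; e[l] += h; double fpp = gfun(d, e);
      e[l] -= 2 * h;        double fpm = gfun(d, e);
      e[k] -= 2 * h;        double fmm = gfun(d, e);
      e[l] += 2 * h;        double fmp = gfun(d, e);
      e[k] += h; e[l] -= h;
      double v = (fpp - fpm - fmp + fmm) / (4.0 * h * h);
      H[k * q + l] = v; H[l * q + k] = v;
    }
}

// expected (Gauss-Newton) information of the conditional normal model:
//   H = sum_j [ f'_j f'_j^T / V_j + (1/2) V'_j V'_j^T / V_j^2 ] + Omega^-1
// with V_j = s2p f_j^2 + s2a and V'_j = 2 s2p f_j f'_j; always PD.
static void hess_gn(const SubjData &d, const std::vector<double> &eta,
                    std::vector<double> &H) {
  int q = eta.size();
  double h = 1e-5;
  int n = d.t.size();
  std::vector<double> e(eta), f0, fp, fm;
  predvec(d, eta, f0);
  std::vector<double> J(n * q);
  for (int k = 0; k < q; ++k) {
    e[k] = eta[k] + h; predvec(d, e, fp);
    e[k] = eta[k] - h; predvec(d, e, fm);
    e[k] = eta[k];
    for (int i = 0; i < n; ++i) J[i * q + k] = (fp[i] - fm[i]) / (2.0 * h);
  }
  std::fill(H.begin(), H.end(), 0.0);
  for (int i = 0; i < n; ++i) {
    double v = d.s2p * f0[i] * f0[i] + d.s2a;
    if (v < 1e-10) v = 1e-10;
    double dv = 2.0 * d.s2p * f0[i];
    for (int k = 0; k < q; ++k)
      for (int l = 0; l < q; ++l)
        H[k * q + l] += J[i * q + k] * J[i * q + l] / v +
          0.5 * (dv * J[i * q + k]) * (dv * J[i * q + l]) / (v * v);
  }
  for (int k = 0; k < q; ++k) {
    double w = d.omega2[k] < 1e-12 ? 1e-12 : d.omega2[k];
    H[k * q + k] += 1.0 / w;
  }
}

static bool chol_small(std::vector<double> &A, int q);

// Jacobi eigendecomposition of a small symmetric matrix: A = R diag(l) R^T
static void jacobi_eigen(std::vector<double> A, int q,
                         std::vector<double> &R, std::vector<double> &lam) {
  R.assign(q * q, 0.0);
  for (int k = 0; k < q; ++k) R[k * q + k] = 1.0;
  for (int sweep = 0; sweep < 50; ++sweep) {
    double off = 0.0;
    for (int p = 0; p < q; ++p)
      for (int r = p + 1; r < q; ++r) off += std::abs(A[p * q + r]);
    if (off < 1e-12) break;
    for (int p = 0; p < q; ++p)
      for (int r = p + 1; r < q; ++r) {
        double apr = A[p * q + r];
        if (std::abs(apr) < 1e-14) continue;
        double theta = 0.5 * (A[r * q + r] - A[p * q + p]) / apr;
        double t = (theta >= 0 ? 1.0 : -1.0) /
          (std::abs(theta) + std::sqrt(theta * theta + 1.0));
        double c = 1.0 / std::sqrt(t * t + 1.0), s = t * c;
        for (int k = 0; k < q; ++k) {
          double akp = A[k * q + p], akr = A[k * q + r];
          A[k * q + p] = c * akp - s * akr;
          A[k * q + r] = s * akp + c * akr;
        }
        for (int k = 0; k < q; ++k) {
          double apk = A[p * q + k], ark = A[r * q + k];
          A[p * q + k] = c * apk - s * ark;
          A[r * q + k] = s * apk + c * ark;
        }
        for (int k = 0; k < q; ++k) {
          double rkp = R[k * q + p], rkr = R[k * q + r];
          R[k * q + p] = c * rkp - s * rkr;
          R[k * q + r] = s * rkp + c * rkr;
        }
      }
  }
  lam.resize(q);
  for (int k = 0; k < q; ++k) lam[k] = A[k * q + k];
}

// Curvature used for the Newton steps and the Laplace determinant: the
// exact Hessian with its spectrum floored, in the metric of the expected
// information, at CURV_FLOOR (continuous in the parameters, always PD,
// and identical to the exact Hessian wherever it dominates the floor —
// the safeguard only engages near flat or merging conditional modes).
static const double CURV_FLOOR = 0.1;

static void grad_hess(const SubjData &d, const std::vector<double> &eta,
                      std::vector<double> &g, std::vector<double> &H) {
  int q = eta.size();
  grad_fd(d, eta, g);
  std::vector<double> Hex(q * q), Hgn(q * q);
  hess_fd(d, eta, Hex);
  hess_gn(d, eta, Hgn);
  std::vector<double> L(Hgn);
  if (!chol_small(L, q)) {  // expected information should be PD; be safe
    H = Hgn;
    for (int k = 0; k < q; ++k) H[k * q + k] += 1e-8;
    return;
  }
  // Linv: inverse of the lower-triangular factor
  std::vector<double> Linv(q * q, 0.0);
  for (int j = 0; j < q; ++j) {
    Linv[j * q + j] = 1.0 / L[j * q + j];
    for (int i = j + 1; i < q; ++i) {
      double s = 0.0;
      for (int k = j; k < i; ++k) s -= L[i * q + k] * Linv[k * q + j];
      Linv[i * q + j] = s / L[i * q + i];
    }
  }
  // M = Linv Hex Linv^T
  std::vector<double> T(q * q, 0.0), M(q * q, 0.0);
  for (int i = 0; i < q; ++i)
    for (int j = 0; j < q; ++j) {
      double s = 0.0;
      for (int k = 0; k <= i; ++k) s += Linv[i * q + k] * Hex[k * q + j];
      T[i * q + j] = s;
    }
  for (int i = 0; i < q; ++i)
    for (int j = 0; j < q; ++j) {
      double s = 0.0;
      for (int k = 0; k <= j; ++k) s += T[i * q + k] * Linv[j * q + k];
      M[i * q + j] = s;
    }
  std::vector<double> R, lam;
  jacobi_eigen(M, q, R, lam);
  for (int k = 0; k < q; ++k) if (lam[k] < CURV_FLOOR) lam[k] = CURV_FLOOR;
  // H = L R diag(lam) R^T L^T
  std::vector<double> LR(q * q, 0.0);
  for (int i = 0; i < q; ++i)
    for (int j = 0; j < q; ++j) {
      double s = 0.0;
      for (int k = 0; k <= i; ++k) s += L[i * q + k] * R[k * q + j];
      LR[i * q + j] = s;
    }
  for (int i = 0; i < q; ++i)
    for (int j = 0; j < q; ++j) {
      double s = 0.0;
      for (int k = 0; k < q; ++k)
        s += LR[i * q + k] * lam[k] * LR[j * q + k];
      H[i * q + j] = s;
    }
}

// Cholesky in place for small q; returns false if not positive definite
static bool chol_small(std::vector<double> &A, int q) {
  for (int j = 0; j < q; ++j) {
    double s = A[j * q + j];
    for (int k = 0; k < j; ++k) s -= A[j * q + k] * A[j * q + k];
    if (s <= 0.0) return false;
    A[j * q + j] = std::sqrt(s);
    for (int i = j + 1; i < q; ++i) {
      double t = A[i * q + j];
      for (int k = 0; k < j; ++k) t -= A[i * q + k] * A[j * q + k];
      A[i * q + j] = t / A[j * q + j];
    }
  }
  return true;
}

static void chol_solve(const std::vector<double> &L, int q,
                       const std::vector<double> &b, std::vector<double> &x) {
  std::vector<double> ytmp(q);
  for (int i = 0; i < q; ++i) {
    double s = b[i];
    for (int k = 0; k < i; ++k) s -= L[i * q + k] * ytmp[k];
    ytmp[i] = s / L[i * q + i];
  }
  for (int i = q - 1; i >= 0; --i) {
    double s = ytmp[i];
    for (int k = i + 1; k < q; ++k) s -= L[k * q + i] * x[k];
    x[i] = s / L[i * q + i];
  }
}

// [[Rcpp::export]]
List cpp_subject_laplace(NumericVector t, NumericVector y, double dose,
                         double tau, int model, double ka, NumericVector ptyp,
                         IntegerVector etaMap, NumericVector omega2,
                         double s2p, double s2a, NumericVector etaStart,
                         double tol, int maxit) {
  SubjData d;
  d.t = t; d.y = y; d.dose = dose; d.tau = tau; d.model = model; d.ka = ka;
  d.ptyp = ptyp; d.etaMap = etaMap; d.omega2 = omega2; d.s2p = s2p; d.s2a = s2a;
  int q = omega2.size();
  const double LOG2PI = 1.8378770664093453;

  if (q == 0) {
    std::vector<double> eta0;
    double ofv = 2.0 * gfun(d, eta0);
    return List::create(_["ofv"] = ofv, _["eta"] = NumericVector(0),
                        _["converged"] = true, _["g"] = ofv / 2.0);
  }

  // The conditional density can be multimodal (large omega2 with
  // proportional error); run Newton from eta = 0 and from +/- one prior SD
  // along each axis, and keep the deepest mode.
  std::vector<std::vector<double> > starts;
  {
    std::vector<double> s0(q);
    for (int k = 0; k < q; ++k) s0[k] = etaStart[k];
    starts.push_back(s0);
    for (int k = 0; k < q; ++k) {
      double sd = std::sqrt(std::max(d.omega2[k], 1e-12));
      std::vector<double> sp(s0), sm(s0);
      sp[k] += sd; sm[k] -= sd;
      starts.push_back(sp);
      starts.push_back(sm);
    }
  }
  std::vector<double> etaBest;
  double fBest = R_PosInf;
  bool convBest = false;
  for (size_t si = 0; si < starts.size(); ++si) {
  std::vector<double> eta(starts[si]);
  std::vector<double> g(q), H(q * q);
  double fcur = gfun(d, eta);
  bool conv = false;
  for (int it = 0; it < maxit; ++it) {
    grad_hess(d, eta, g, H);
    double gmax = 0.0;
    for (int k = 0; k < q; ++k) gmax = std::max(gmax, std::abs(g[k]));
    if (gmax < tol) { conv = true; break; }
    // Newton step with Levenberg damping until the factorization succeeds
    std::vector<double> step(q), L;
    double lambda = 0.0;
    for (int attempt = 0; attempt < 8; ++attempt) {
      L = H;
      for (int k = 0; k < q; ++k) L[k * q + k] += lambda;
      if (chol_small(L, q)) break;
      lambda = lambda == 0.0 ? 1e-4 : lambda * 10.0;
      if (attempt == 7) {  // fall back to scaled gradient descent
        for (int k = 0; k < q; ++k) { L.assign(q * q, 0.0); }
        for (int k = 0; k < q; ++k) L[k * q + k] = 1.0;
        break;
      }
    }
    chol_solve(L, q, g, step);
    // line search (halving) on the Newton direction
    double alpha = 1.0;
    std::vector<double> trial(q);
    bool moved = false;
    for (int ls = 0; ls < 30; ++ls) {
      for (int k = 0; k < q; ++k) trial[k] = eta[k] - alpha * step[k];
      double ftr = gfun(d, trial);
      if (ftr < fcur) { eta = trial; fcur = ftr; moved = true; break; }
      alpha *= 0.5;
    }
    if (!moved) { conv = true; break; }  // no descent possible: at mode
  }
  if (fcur < fBest) { fBest = fcur; etaBest = eta; convBest = conv; }
  }
  std::vector<double> eta(etaBest);
  double fcur = fBest;
  bool conv = convBest;
  std::vector<double> g(q), H(q * q);
  // Laplace: -2 log L = 2 g(eta^) - q log(2 pi) + log det H(eta^)
  grad_hess(d, eta, g, H);
  std::vector<double> L(H);
  double ridge = 0.0;
  while (!chol_small(L, q)) {
    ridge = ridge == 0.0 ? 1e-8 : ridge * 10.0;
    L = H;
    for (int k = 0; k < q; ++k) L[k * q + k] += ridge;
    if (ridge > 1.0) break;
  }
  double logdet = 0.0;
  for (int k = 0; k < q; ++k) logdet += 2.0 * std::log(L[k * q + k]);
  double ofv = 2.0 * fcur - q * LOG2PI + logdet;
  NumericVector etaOut(q);
  for (int k = 0; k < q; ++k) etaOut[k] = eta[k];
  return List::create(_["ofv"] = ofv, _["eta"] = etaOut,
                      _["converged"] = conv, _["g"] = fcur);
}

// Whole-study objective: the per-subject Laplace loop in one call.
// obsStart gives the 0-based offset of each subject's observations in the
// flattened (t, y) vectors (length nsub + 1, last element = total count);
// ptyp is an (npar x nsub) matrix of covariate-adjusted typical values.
// [[Rcpp::export]]
List cpp_study_laplace(IntegerVector obsStart, NumericVector t,
                       NumericVector y, NumericVector dose,
                       NumericVector tau, int model, double ka,
                       NumericMatrix ptyp, IntegerVector etaMap,
                       NumericVector omega2, double s2p, double s2a,
                       double tol, int maxit) {
  int nsub = obsStart.size() - 1;
  int q = omega2.size();
  const double LOG2PI = 1.8378770664093453;
  NumericVector per(nsub);
  NumericMatrix etas(nsub, q);
  LogicalVector conv(nsub);
  NumericVector etaStart(q);
  double total = 0.0;
  for (int i = 0; i < nsub; ++i) {
    int a = obsStart[i], b = obsStart[i + 1];
    NumericVector ti(b - a), yi(b - a), pi(ptyp.nrow());
    for (int j = a; j < b; ++j) { ti[j - a] = t[j]; yi[j - a] = y[j]; }
    for (int k = 0; k < ptyp.nrow(); ++k) pi[k] = ptyp(k, i);
    List res = cpp_subject_laplace(ti, yi, dose[i], tau[i], model, ka, pi,
                                   etaMap, omega2, s2p, s2a, etaStart, tol,
                                   maxit);
    double o = as<double>(res["ofv"]);
    per[i] = o;
    total += o;
    conv[i] = as<bool>(res["converged"]);
    if (q > 0 && (b - a) > 0) {
      NumericVector e = res["eta"];
      for (int k = 0; k < q; ++k) etas(i, k) = e[k];
    }
  }
  return List::create(_["ofv"] = total, _["perSubject"] = per,
                      _["etas"] = etas, _["converged"] = conv);
}
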