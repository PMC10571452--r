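// Joint likelihood of the bivariate linear mixed sub-model and the
// piecewise-exponential proportional-hazards sub-model.
//
// For subject i with stacked longitudinal vector y_i (both outcomes),
// random effects b = (b_PR0, b_PR1, b_BT0, b_BT1) ~ N(0, D), the
// contribution is
//   log integral  N(y_i | X_i beta + Z_i b, R_i)
//               * [h_i(T_i|b)]^delta_i * exp(-Lambda_i(T_i|b))
//               * N(b | 0, D) db .
// The Gaussian part integrates in closed form, leaving the expectation of
// the survival factor under the longitudinal posterior b | y_i ~ N(m, Vp).
// In every supported association structure the log hazard is
//   log h_i(t|b) = log lambda_0(t) + u(b) + v(b) t
// with u, v *linear* in b, so the survival factor depends on b only
// through the bivariate Gaussian image (u, v): the 4-dim integral reduces
// exactly to adaptive Gauss-Hermite quadrature in <= 2 dimensions.
//
// The Gaussian algebra uses the Woodbury identity on the 4x4 matrix
// M = D^-1 + Z' R^-1 Z when D is invertible (O(ni) per subject), with a
// dense ni x ni Cholesky fallback for singular D.
//
// assoc: 1 = current value, 2 = current value and slope,
//        3 = shared random effects (random slopes), 0 = none.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double LOG2PI = 1.8378770664093454836;

// cumulative hazard int_0^T lambda(s) exp(u + v s) ds, piecewise rates
static double cumhaz(double T, double u, double v,
                     const arma::vec& lam, const arma::vec& lo,
                     const arma::vec& hi) {
  double S = 0.0;
  for (arma::uword p = 0; p < lam.n_elem; ++p) {
    double b = std::min(T, hi[p]);
    if (b <= lo[p]) break;
    if (std::abs(v) < 1e-12)
      S += lam[p] * (b - lo[p]);
    else
      S += lam[p] * std::exp(v * lo[p]) * std::expm1(v * (b - lo[p])) / v;
  }
  return std::exp(u) * S;
}

static double base_rate(double T, const arma::vec& lam, const arma::vec& lo) {
  arma::uword p = lam.n_elem - 1;
  for (arma::uword j = 1; j < lam.n_elem; ++j)
    if (T <= lo[j]) { p = j - 1; break; }
  return lam[p];
}

static inline double lse2(double a, double b) {
  if (a == -std::numeric_limits<double>::infinity()) return b;
  return (a > b) ? a + std::log1p(std::exp(b - a))
                 : b + std::log1p(std::exp(a - b));
}

// [[Rcpp::export]]
List jm_nll_cpp(List dat, List par, int assoc, int nq,
                bool survival, bool profile, bool details) {
  arma::ivec lstart = as<arma::ivec>(dat["long_start"]); // 1-based, 0 if none
  arma::ivec lend   = as<arma::ivec>(dat["long_end"]);
  arma::ivec kvec   = as<arma::ivec>(dat["k"]);
  arma::vec  tvec   = as<arma::vec>(dat["t"]);
  arma::vec  yvec   = as<arma::vec>(dat["y"]);
  arma::mat  X      = as<arma::mat>(dat["X"]);
  arma::mat  Xs1    = as<arma::mat>(dat["Xs1"]);
  arma::mat  Xs2    = as<arma::mat>(dat["Xs2"]);
  int tc1 = as<int>(dat["tc1"]) - 1;
  int tc2 = as<int>(dat["tc2"]) - 1;
  arma::mat  W      = as<arma::mat>(dat["W"]);
  arma::vec  Tv     = as<arma::vec>(dat["Tv"]);
  arma::vec  delta  = as<arma::vec>(dat["delta"]);
  arma::vec  cut    = as<arma::vec>(dat["cut"]);
  arma::vec  ghx    = as<arma::vec>(dat["ghx"]);
  arma::vec  ghw    = as<arma::vec>(dat["ghw"]);

  arma::vec beta  = as<arma::vec>(par["beta"]);
  arma::vec sig2  = as<arma::vec>(par["sig2"]);
  arma::mat D     = as<arma::mat>(par["D"]);
  arma::vec gamma = as<arma::vec>(par["gamma"]);
  arma::vec alpha = as<arma::vec>(par["alpha"]);
  arma::vec lam   = as<arma::vec>(par["lam"]);

  const int n = Tv.n_elem;
  const int p = X.n_cols;
  arma::vec lo(lam.n_elem), hi(lam.n_elem);
  for (arma::uword j = 0; j < lam.n_elem; ++j) {
    lo[j] = (j == 0) ? 0.0 : cut[j - 1];
    hi[j] = (j + 1 < lam.n_elem) ? cut[j] : std::numeric_limits<double>::infinity();
  }

  bool ok = D.is_finite() && sig2.is_finite() && sig2.min() > 0;

  // Woodbury pieces for invertible D (computed once)
  bool useD = false;
  arma::mat Dinv(4, 4);
  double logdetD = 0.0;
  if (ok) {
    arma::mat Ld;
    D = 0.5 * (D + D.t());
    // Woodbury needs a well-conditioned D inverse; near-singular D falls
    // back to the dense per-subject path, which never inverts D
    if (arma::chol(Ld, D, "lower") &&
        Ld.diag().min() > 1e-5 * Ld.diag().max()) {
      useD = true;
      arma::mat I4 = arma::eye(4, 4);
      arma::mat tmp = arma::solve(arma::trimatl(Ld), I4);
      Dinv = arma::solve(arma::trimatu(Ld.t()), tmp);
      logdetD = 2.0 * arma::sum(arma::log(Ld.diag()));
    }
  }

  arma::vec rall = profile ? yvec : yvec - X * beta;

  arma::vec ll_long(n, arma::fill::zeros), ll_surv(n, arma::fill::zeros);
  arma::mat post_mean(details ? n : 0, 4);
  arma::mat post_var(details ? n : 0, 16);
  arma::mat A(profile ? p : 0, profile ? p : 0, arma::fill::zeros);
  arma::vec bvec(profile ? p : 0, arma::fill::zeros);
  double quadsum = 0.0, ldetsum = 0.0;
  int ntot = 0;

  for (int i = 0; i < n && ok; ++i) {
    int s = lstart[i] - 1, e = lend[i] - 1;
    int ni = (lstart[i] > 0) ? (e - s + 1) : 0;
    arma::vec m(4, arma::fill::zeros);
    arma::mat Vp = D;

    if (ni > 0) {
      arma::mat Zi(ni, 4, arma::fill::zeros);
      arma::vec Ri(ni);
      for (int j = 0; j < ni; ++j) {
        int kk = kvec[s + j];                   // 1 or 2
        Zi(j, 2 * (kk - 1))     = 1.0;
        Zi(j, 2 * (kk - 1) + 1) = tvec[s + j];
        Ri[j] = sig2[kk - 1];
      }
      arma::vec ri = rall.subvec(s, e);
      double ldet, quad;

      if (useD) {
        // Woodbury: all heavy algebra on the 4x4 scale
        arma::vec rinv = 1.0 / Ri;
        arma::mat Zw = Zi.each_col() % rinv;     // R^-1 Z
        arma::mat ZtRZ = Zi.t() * Zw;
        arma::vec ZtRr = Zw.t() * ri;
        double rtRr = arma::dot(ri % rinv, ri);
        double logdetR = arma::sum(arma::log(Ri));
        arma::mat M = Dinv + ZtRZ;
        M = 0.5 * (M + M.t());
        arma::mat LM;
        if (!arma::chol(LM, M, "lower") ||
            LM.diag().min() < 1e-12 * LM.diag().max()) { ok = false; break; }
        arma::vec w2 = arma::solve(arma::trimatl(LM), ZtRr);
        ldet = 2.0 * arma::sum(arma::log(LM.diag())) + logdetD + logdetR;
        quad = rtRr - arma::dot(w2, w2);
        ll_long[i] = -0.5 * (ni * LOG2PI + ldet + quad);
        // posterior: Vp = M^-1, m = M^-1 Z'R^-1 r
        arma::mat tmp = arma::solve(arma::trimatl(LM), arma::eye(4, 4));
        Vp = arma::solve(arma::trimatu(LM.t()), tmp);
        m = Vp * ZtRr;
        if (profile) {
          arma::mat Xi = X.rows(s, e);
          arma::mat ZtRX = Zw.t() * Xi;             // 4 x p
          arma::mat Xw = Xi.each_col() % rinv;
          arma::mat UX = arma::solve(arma::trimatl(LM), ZtRX);
          A += Xw.t() * Xi - UX.t() * UX;
          bvec += Xw.t() * ri - UX.t() * w2;
          quadsum += quad; ldetsum += ldet; ntot += ni;
        }
      } else {
        // dense fallback (singular D, e.g. exactly zero blocks)
        arma::mat V = Zi * D * Zi.t();
        V = 0.5 * (V + V.t());
        V.diag() += Ri;
        arma::mat L;
        if (!V.is_finite() || !arma::chol(L, V, "lower") ||
            L.diag().min() < 1e-10 * L.diag().max()) { ok = false; break; }
        arma::vec w = arma::solve(arma::trimatl(L), ri);
        ldet = 2.0 * arma::sum(arma::log(L.diag()));
        quad = arma::dot(w, w);
        ll_long[i] = -0.5 * (ni * LOG2PI + ldet + quad);
        arma::mat U = arma::solve(arma::trimatl(L), Zi);   // ni x 4
        arma::vec Ztr = U.t() * w;
        arma::mat ZtZ = U.t() * U;
        m  = D * Ztr;
        Vp = D - D * ZtZ * D;
        if (profile) {
          arma::mat Xi = X.rows(s, e);
          arma::mat UX = arma::solve(arma::trimatl(L), Xi);
          A += UX.t() * UX;
          bvec += UX.t() * w;
          quadsum += quad; ldetsum += ldet; ntot += ni;
        }
      }
    }
    if (details) {
      post_mean.row(i) = m.t();
      post_var.row(i) = arma::vectorise(Vp).t();
    }

    if (survival) {
      double f1 = arma::dot(Xs1.row(i), beta);
      double f2 = arma::dot(Xs2.row(i), beta);
      double g1 = beta[tc1], g2 = beta[tc2];
      double gw = (gamma.n_elem > 0) ? arma::dot(W.row(i), gamma) : 0.0;
      double s0 = gw, r0 = 0.0;
      arma::vec sv(4, arma::fill::zeros), rv(4, arma::fill::zeros);
      if (assoc == 1 && alpha.n_elem >= 2) {          // current value
        s0 += alpha[0] * f1 + alpha[1] * f2;
        sv[0] = alpha[0]; sv[2] = alpha[1];
        r0 = alpha[0] * g1 + alpha[1] * g2;
        rv[1] = alpha[0]; rv[3] = alpha[1];
      } else if (assoc == 2 && alpha.n_elem >= 4) {   // current value and slope
        s0 += alpha[0] * f1 + alpha[1] * f2 + alpha[2] * g1 + alpha[3] * g2;
        sv[0] = alpha[0]; sv[2] = alpha[1];
        sv[1] = alpha[2]; sv[3] = alpha[3];
        r0 = alpha[0] * g1 + alpha[1] * g2;
        rv[1] = alpha[0]; rv[3] = alpha[1];
      } else if (assoc == 3 && alpha.n_elem >= 2) {   // shared random slopes
        sv[1] = alpha[0]; sv[3] = alpha[1];
      }
      double mu_u = s0 + arma::dot(sv, m);
      double mu_v = r0 + arma::dot(rv, m);
      arma::mat C(2, 2);
      C(0, 0) = arma::as_scalar(sv.t() * Vp * sv);
      C(1, 1) = arma::as_scalar(rv.t() * Vp * rv);
      C(0, 1) = C(1, 0) = arma::as_scalar(sv.t() * Vp * rv);

      arma::vec eval;
      arma::mat evec;
      if (!arma::eig_sym(eval, evec, 0.5 * (C + C.t()))) { ok = false; break; }
      const double tol = 1e-10 * std::max(1.0, eval.max());
      std::vector<int> act;
      for (int d = 0; d < 2; ++d) if (eval[d] > tol) act.push_back(d);
      int nd = act.size();

      double Ti = Tv[i], di = delta[i];
      double lrate = std::log(base_rate(Ti, lam, lo));
      double lse = -std::numeric_limits<double>::infinity();
      if (nd == 0) {
        lse = di * (lrate + mu_u + mu_v * Ti)
            - cumhaz(Ti, mu_u, mu_v, lam, lo, hi);
      } else if (nd == 1) {
        double a0 = evec(0, act[0]) * std::sqrt(eval[act[0]]);
        double a1 = evec(1, act[0]) * std::sqrt(eval[act[0]]);
        for (arma::uword q = 0; q < ghx.n_elem; ++q) {
          double u = mu_u + a0 * ghx[q], v = mu_v + a1 * ghx[q];
          double lg = di * (lrate + u + v * Ti) - cumhaz(Ti, u, v, lam, lo, hi)
                    + std::log(ghw[q]);
          lse = lse2(lse, lg);
        }
      } else {
        double a00 = evec(0, act[0]) * std::sqrt(eval[act[0]]);
        double a10 = evec(1, act[0]) * std::sqrt(eval[act[0]]);
        double a01 = evec(0, act[1]) * std::sqrt(eval[act[1]]);
        double a11 = evec(1, act[1]) * std::sqrt(eval[act[1]]);
        for (arma::uword q1 = 0; q1 < ghx.n_elem; ++q1) {
          double lw1 = std::log(ghw[q1]);
          for (arma::uword q2 = 0; q2 < ghx.n_elem; ++q2) {
            double u = mu_u + a00 * ghx[q1] + a01 * ghx[q2];
            double v = mu_v + a10 * ghx[q1] + a11 * ghx[q2];
            double lg = di * (lrate + u + v * Ti)
                      - cumhaz(Ti, u, v, lam, lo, hi)
                      + lw1 + std::log(ghw[q2]);
            lse = lse2(lse, lg);
          }
        }
      }
      ll_surv[i] = lse;
    }
  }

  double nll;
  arma::vec beta_hat;
  arma::mat beta_vcov;
  if (!ok) {
    nll = std::numeric_limits<double>::infinity();
  } else if (profile) {
    A = 0.5 * (A + A.t());
    arma::mat Ainv;
    if (!arma::inv_sympd(Ainv, A)) {
      nll = std::numeric_limits<double>::infinity();
    } else {
      beta_hat = Ainv * bvec;
      beta_vcov = Ainv;
      double quad = quadsum - arma::dot(bvec, beta_hat);
      nll = 0.5 * (ntot * LOG2PI + ldetsum + quad);
    }
  } else {
    nll = -(arma::sum(ll_long) + arma::sum(ll_surv));
    if (!std::isfinite(nll)) nll = std::numeric_limits<double>::infinity();
  }

  List out = List::create(_["nll"] = nll,
                          _["ll_long"] = ll_long,
                          _["ll_surv"] = ll_surv);
  if (profile && beta_hat.n_elem > 0) {
    out["beta_hat"] = beta_hat;
    out["beta_vcov"] = beta_vcov;
  }
  if (details) {
    out["post_mean"] = post_mean;
    out["post_var"] = post_var;
  }
  return out;
}
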