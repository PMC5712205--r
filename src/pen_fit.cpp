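#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Penalised per-patient fits for the biexponential SLD model on the log
// parameter scale. For patient i with observations (t_j, y_j):
//   J(p) = sum_j (y_j - f(t_j; exp(p)))^2 / (2 sigma^2)
//        + sum_k (p_k - mu_k)^2 / (2 omega2_k)
// minimised by a Levenberg-damped Gauss-Newton scheme with analytic
// gradient. The Gauss-Newton Hessian (G'G/sigma^2 + diag(1/omega2)) also
// provides the curvature used for the first-order (Laplace-style)
// variance corrections returned to the outer population loop.

// log-scale box keeping exp() finite and parameters physiological:
// A in [e^-6, e^7] cm, B and C in [e^-14, e^2] per week.
static const double LO[3] = {-6.0, -14.0, -14.0};
static const double HI[3] = { 7.0,   2.0,   2.0};

static inline double clampd(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

struct Work {
  const double *t, *y;
  int m;
  double s2;
  const double *mu, *om2;
};

static double objective(const Work &w, const double p[3]) {
  double A = std::exp(p[0]), B = std::exp(p[1]), C = std::exp(p[2]);
  double rss = 0.0;
  for (int j = 0; j < w.m; ++j) {
    double f = A * (std::exp(-B * w.t[j]) + std::exp(C * w.t[j]) - 1.0);
    double r = w.y[j] - f;
    rss += r * r;
  }
  double pen = 0.0;
  for (int k = 0; k < 3; ++k) {
    double d = p[k] - w.mu[k];
    pen += d * d / (2.0 * w.om2[k]);
  }
  return rss / (2.0 * w.s2) + pen;
}

// gradient, GN Hessian and rss at p
static void derivs(const Work &w, const double p[3], double g[3], double H[9],
                   double *rss_out) {
  double A = std::exp(p[0]), B = std::exp(p[1]), C = std::exp(p[2]);
  double gr[3] = {0, 0, 0};
  double h[9] = {0, 0, 0, 0, 0, 0, 0, 0, 0};
  double rss = 0.0;
  for (int j = 0; j < w.m; ++j) {
    double tj = w.t[j];
    double e1 = std::exp(-B * tj), e2 = std::exp(C * tj);
    double f = A * (e1 + e2 - 1.0);
    double r = w.y[j] - f;
    rss += r * r;
    double G[3];
    G[0] = f;                  // df/d log A
    G[1] = -A * B * tj * e1;   // df/d log B
    G[2] =  A * C * tj * e2;   // df/d log C
    for (int k = 0; k < 3; ++k) {
      gr[k] -= r * G[k];
      for (int l = 0; l <= k; ++l) h[3 * k + l] += G[k] * G[l];
    }
  }
  for (int k = 0; k < 3; ++k) {
    g[k] = gr[k] / w.s2 + (p[k] - w.mu[k]) / w.om2[k];
    for (int l = 0; l <= k; ++l) {
      H[3 * k + l] = h[3 * k + l] / w.s2;
      H[3 * l + k] = H[3 * k + l];
    }
    H[3 * k + k] += 1.0 / w.om2[k];
  }
  *rss_out = rss;
}

// solve 3x3 symmetric positive definite system via Cholesky; returns false
// if not positive definite
static bool solve3(const double H[9], const double b[3], double x[3]) {
  double L[9] = {0};
  for (int i = 0; i < 3; ++i) {
    for (int j = 0; j <= i; ++j) {
      double s = H[3 * i + j];
      for (int k = 0; k < j; ++k) s -= L[3 * i + k] * L[3 * j + k];
      if (i == j) {
        if (s <= 0) return false;
        L[3 * i + i] = std::sqrt(s);
      } else {
        L[3 * i + j] = s / L[3 * j + j];
      }
    }
  }
  double z[3];
  for (int i = 0; i < 3; ++i) {
    double s = b[i];
    for (int k = 0; k < i; ++k) s -= L[3 * i + k] * z[k];
    z[i] = s / L[3 * i + i];
  }
  for (int i = 2; i >= 0; --i) {
    double s = z[i];
    for (int k = i + 1; k < 3; ++k) s -= L[3 * k + i] * x[k];
    x[i] = s / L[3 * i + i];
  }
  return true;
}

static bool inv3(const double H[9], double V[9], double *logdet) {
  // adjugate inverse of symmetric 3x3
  double a = H[0], b = H[1], c = H[2], d = H[4], e = H[5], f = H[8];
  // matrix [[a,b,c],[b,d,e],[c,e,f]]
  double A11 = d * f - e * e, A12 = c * e - b * f, A13 = b * e - c * d;
  double det = a * A11 + b * A12 + c * A13;
  if (!(det > 0)) return false;
  double A22 = a * f - c * c, A23 = b * c - a * e, A33 = a * d - b * b;
  V[0] = A11 / det; V[1] = A12 / det; V[2] = A13 / det;
  V[3] = A12 / det; V[4] = A22 / det; V[5] = A23 / det;
  V[6] = A13 / det; V[7] = A23 / det; V[8] = A33 / det;
  *logdet = std::log(det);
  return true;
}

// [[Rcpp::export(name = ".fit_patients_cpp")]]
List fit_patients_cpp(List times, List sld, NumericMatrix lp_init,
                      NumericVector mu, NumericVector om2, double sigma2,
                      int max_inner = 100, double gtol = 1e-9) {
  int n = times.size();
  NumericMatrix lp_out(3, n), vdiag(3, n);
  NumericVector obj(n), logdet(n), rss_pat(n);
  double rss_tot = 0.0, corr_tot = 0.0;
  int nobs_tot = 0;

  for (int i = 0; i < n; ++i) {
    NumericVector ti = times[i], yi = sld[i];
    Work w;
    w.t = ti.begin(); w.y = yi.begin(); w.m = ti.size();
    w.s2 = sigma2; w.mu = mu.begin(); w.om2 = om2.begin();
    nobs_tot += w.m;

    double p[3];
    for (int k = 0; k < 3; ++k) p[k] = clampd(lp_init(k, i), LO[k], HI[k]);
    double J = objective(w, p);
    double lambda = 1e-3;

    for (int it = 0; it < max_inner; ++it) {
      double g[3], H[9], rssv;
      derivs(w, p, g, H, &rssv);
      double gmax = std::max(std::fabs(g[0]),
                    std::max(std::fabs(g[1]), std::fabs(g[2])));
      if (gmax < gtol) break;
      bool moved = false;
      for (int tries = 0; tries < 40; ++tries) {
        double Hd[9];
        for (int k = 0; k < 9; ++k) Hd[k] = H[k];
        for (int k = 0; k < 3; ++k) Hd[3 * k + k] = H[3 * k + k] * (1.0 + lambda);
        double nb[3] = {-g[0], -g[1], -g[2]}, dp[3];
        if (!solve3(Hd, nb, dp)) { lambda *= 10.0; continue; }
        double pn[3];
        for (int k = 0; k < 3; ++k) pn[k] = clampd(p[k] + dp[k], LO[k], HI[k]);
        double Jn = objective(w, pn);
        if (Jn < J) {
          double step = std::fabs(pn[0] - p[0]) + std::fabs(pn[1] - p[1]) +
                        std::fabs(pn[2] - p[2]);
          for (int k = 0; k < 3; ++k) p[k] = pn[k];
          bool tiny = (J - Jn) < 1e-14 * (1.0 + std::fabs(J)) && step < 1e-10;
          J = Jn;
          lambda = std::max(lambda * 0.35, 1e-12);
          moved = true;
          if (tiny) it = max_inner; // converged by stagnation
          break;
        }
        lambda *= 6.0;
        if (lambda > 1e12) break;
      }
      if (!moved) break;
    }

    double g[3], H[9], rssv;
    derivs(w, p, g, H, &rssv);
    double V[9], ld;
    double corr_i = 0.0;
    if (inv3(H, V, &ld)) {
      // correction: sum_j G_j' V G_j at the mode (parameter-uncertainty
      // contribution to the residual variance update)
      double A = std::exp(p[0]), B = std::exp(p[1]), C = std::exp(p[2]);
      for (int j = 0; j < w.m; ++j) {
        double tj = w.t[j];
        double e1 = std::exp(-B * tj), e2 = std::exp(C * tj);
        double G[3];
        G[0] = A * (e1 + e2 - 1.0);
        G[1] = -A * B * tj * e1;
        G[2] =  A * C * tj * e2;
        double q = 0.0;
        for (int k = 0; k < 3; ++k)
          for (int l = 0; l < 3; ++l) q += G[k] * V[3 * k + l] * G[l];
        corr_i += q;
      }
      for (int k = 0; k < 3; ++k) vdiag(k, i) = V[3 * k + k];
      logdet[i] = ld;
    } else {
      for (int k = 0; k < 3; ++k) vdiag(k, i) = 0.0;
      logdet[i] = R_PosInf;
    }
    for (int k = 0; k < 3; ++k) lp_out(k, i) = p[k];
    obj[i] = J;
    rss_pat[i] = rssv;
    rss_tot += rssv;
    corr_tot += corr_i;
  }

  return List::create(_["lp"] = lp_out, _["vdiag"] = vdiag, _["obj"] = obj,
                      _["logdet"] = logdet, _["rss"] = rss_tot,
                      _["rss_patient"] = rss_pat,
                      _["corr"] = corr_tot, _["n_obs"] = nobs_tot);
}
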