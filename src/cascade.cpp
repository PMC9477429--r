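#include <Rcpp.h>
using namespace Rcpp;

// Five-state biomarker cascade:
//   x = (Abeta, taup, tauo, N, C)
// with anti-amyloid clearance u(t) acting multiplicatively on Abeta.
// All integration is classical fixed-step RK4 on the supplied (uniform)
// grid so that forward states and backward adjoints share one grid.

static inline void cascade_rhs_c(const double *p, const double *y, double u,
                                 double *dy) {
  const double lamA = p[0], KA = p[1], lamT = p[2], KTp = p[3], lamTo = p[4],
               lamNTo = p[5], lamNTp = p[6], KN = p[7], lamCN = p[8],
               lamCT = p[9], KC = p[10];
  dy[0] = lamA * y[0] * (1.0 - y[0] / KA) - u * y[0];
  dy[1] = lamT * y[0] * (1.0 - y[1] / KTp);
  dy[2] = lamTo;
  dy[3] = (lamNTo * y[2] + lamNTp * y[1]) * (1.0 - y[3] / KN);
  dy[4] = (lamCN * y[3] + lamCT * y[1]) * (1.0 - y[4] / KC);
}

// [[Rcpp::export]]
List cascade_integrate_cpp(NumericVector par, NumericVector y0,
                           NumericVector times, NumericVector u,
                           double neg_tol) {
  const int n = times.size();
  NumericMatrix out(n, 5);
  double y[5], k1[5], k2[5], k3[5], k4[5], tmp[5];
  const double *p = REAL(par);
  for (int j = 0; j < 5; ++j) { y[j] = y0[j]; out(0, j) = y[j]; }
  for (int i = 0; i < n - 1; ++i) {
    const double h = times[i + 1] - times[i];
    const double u0 = u[i], u1 = u[i + 1], um = 0.5 * (u0 + u1);
    cascade_rhs_c(p, y, u0, k1);
    for (int j = 0; j < 5; ++j) tmp[j] = y[j] + 0.5 * h * k1[j];
    cascade_rhs_c(p, tmp, um, k2);
    for (int j = 0; j < 5; ++j) tmp[j] = y[j] + 0.5 * h * k2[j];
    cascade_rhs_c(p, tmp, um, k3);
    for (int j = 0; j < 5; ++j) tmp[j] = y[j] + h * k3[j];
    cascade_rhs_c(p, tmp, u1, k4);
    for (int j = 0; j < 5; ++j) {
      y[j] += h / 6.0 * (k1[j] + 2.0 * k2[j] + 2.0 * k3[j] + k4[j]);
      if (y[j] < 0.0) {
        if (y[j] > -neg_tol) {
          y[j] = 0.0;  // round-off guard
        } else {
          return List::create(_["states"] = out, _["status"] = 1,
                              _["bad_time"] = times[i + 1],
                              _["component"] = j + 1);
        }
      }
      if (!R_finite(y[j]))
        return List::create(_["states"] = out, _["status"] = 2,
                            _["bad_time"] = times[i + 1],
                            _["component"] = j + 1);
      out(i + 1, j) = y[j];
    }
  }
  return List::create(_["states"] = out, _["status"] = 0,
                      _["bad_time"] = NA_REAL, _["component"] = NA_INTEGER);
}

// Adjoint (costate) right-hand side, dL/dt = -dH/dx for the Hamiltonian
//   H = C + eps0*Abeta*exp(-gamma*(t - t_ref))*u^2 + L' G(x, u).
// `derived = false` reproduces the reduced published variant in which
// dL5/dt keeps only the lamCN*N/KC feedback term.
static inline void adjoint_rhs_c(const double *p, const double *y,
                                 const double *L, double u, double t_rel,
                                 double eps0, double gamma, bool derived,
                                 double *dL) {
  const double lamA = p[0], KA = p[1], lamT = p[2], KTp = p[3],
               lamNTo = p[5], lamNTp = p[6], KN = p[7], lamCN = p[8],
               lamCT = p[9], KC = p[10];
  const double A = y[0], taup = y[1], tauo = y[2], N = y[3], C = y[4];
  dL[0] = -eps0 * std::exp(-gamma * t_rel) * u * u +
          L[0] * (2.0 * lamA * A / KA - lamA + u) -
          L[1] * lamT * (1.0 - taup / KTp);
  dL[1] = L[1] * lamT * A / KTp - L[3] * lamNTp * (1.0 - N / KN) -
          L[4] * lamCT * (1.0 - C / KC);
  dL[2] = -L[3] * lamNTo * (1.0 - N / KN);
  dL[3] = L[3] * (lamNTo * tauo + lamNTp * taup) / KN -
          L[4] * lamCN * (1.0 - C / KC);
  dL[4] = -1.0 + L[4] * lamCN * N / KC;
  if (derived) dL[4] += L[4] * lamCT * taup / KC;
}

// Backward RK4 integration of the adjoint system on the same grid as the
// forward states; states and control are linearly interpolated at half
// steps. Terminal conditions L(T2) = (alpha1, 0, 0, 0, alpha2).
// [[Rcpp::export]]
NumericMatrix adjoint_integrate_cpp(NumericVector par, NumericMatrix states,
                                    NumericVector times, NumericVector u,
                                    double eps0, double gamma, double alpha1,
                                    double alpha2, double t_ref,
                                    bool derived) {
  const int n = times.size();
  NumericMatrix out(n, 5);
  double L[5], k1[5], k2[5], k3[5], k4[5], tmp[5], ya[5], yb[5], ym[5];
  const double *p = REAL(par);
  L[0] = alpha1; L[1] = 0.0; L[2] = 0.0; L[3] = 0.0; L[4] = alpha2;
  for (int j = 0; j < 5; ++j) out(n - 1, j) = L[j];
  for (int i = n - 1; i > 0; --i) {
    const double h = times[i - 1] - times[i];  // negative step
    const double ua = u[i], ub = u[i - 1], um = 0.5 * (ua + ub);
    for (int j = 0; j < 5; ++j) {
      ya[j] = states(i, j);
      yb[j] = states(i - 1, j);
      ym[j] = 0.5 * (ya[j] + yb[j]);
    }
    const double ta = times[i] - t_ref, tb = times[i - 1] - t_ref,
                 tm = 0.5 * (ta + tb);
    adjoint_rhs_c(p, ya, L, ua, ta, eps0, gamma, derived, k1);
    for (int j = 0; j < 5; ++j) tmp[j] = L[j] + 0.5 * h * k1[j];
    adjoint_rhs_c(p, ym, tmp, um, tm, eps0, gamma, derived, k2);
    for (int j = 0; j < 5; ++j) tmp[j] = L[j] + 0.5 * h * k2[j];
    adjoint_rhs_c(p, ym, tmp, um, tm, eps0, gamma, derived, k3);
    for (int j = 0; j < 5; ++j) tmp[j] = L[j] + h * k3[j];
    adjoint_rhs_c(p, yb, tmp, ub, tb, eps0, gamma, derived, k4);
    for (int j = 0; j < 5; ++j) {
      L[j] += h / 6.0 * (k1[j] + 2.0 * k2[j] + 2.0 * k3[j] + k4[j]);
      out(i - 1, j) = L[j];
    }
  }
  return out;
}
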