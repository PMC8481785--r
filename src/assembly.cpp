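// Element and facet assembly kernels for the quasi-static biventricular
// solver. P1 displacement / P1 pressure, single-point quadrature for the
// (constant-gradient) volume terms, exact P1 mass matrix for the pressure
// equation, facet-centroid quadrature for surface terms. Consistent tangents
// are built from central finite differences of the analytic local residuals.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// C1 smoothing of the positive part over a thin blend zone: exactly zero
// below the threshold, quadratic on (0, eps), shifted linear above. Keeps
// the tension-only switches of the fibre and active terms while removing
// the derivative kink that stalls Newton near the transition.
static const double kPosEps = 1e-3;
static inline void pospart_smooth(double x, double& e, double& de) {
  if (x <= 0)            { e = 0;                     de = 0; }
  else if (x < kPosEps)  { e = x * x / (2 * kPosEps); de = x / kPosEps; }
  else                   { e = x - kPosEps / 2;       de = 1; }
}

static inline double det3(const double F[9]) {
  return F[0] * (F[4] * F[8] - F[5] * F[7]) -
         F[3] * (F[1] * F[8] - F[2] * F[7]) +
         F[6] * (F[1] * F[5] - F[2] * F[4]);
}
// column-major 3x3 inverse-transpose times scalar
static inline void invT3(const double F[9], double J, double FinvT[9]) {
  double c[9];
  c[0] = F[4] * F[8] - F[5] * F[7];
  c[1] = F[5] * F[6] - F[3] * F[8];
  c[2] = F[3] * F[7] - F[4] * F[6];
  c[3] = F[7] * F[2] - F[8] * F[1];
  c[4] = F[8] * F[0] - F[6] * F[2];
  c[5] = F[6] * F[1] - F[7] * F[0];
  c[6] = F[1] * F[5] - F[2] * F[4];
  c[7] = F[2] * F[3] - F[0] * F[5];
  c[8] = F[0] * F[4] - F[1] * F[3];
  // cofactor matrix c is already the transpose-inverse numerator: inv(F)^T = cof(F)/J
  for (int i = 0; i < 9; ++i) FinvT[i] = c[i] / J;
}

struct ElemCtx {
  double G[12];     // shape gradients, G[a*3+j]
  double V;         // reference volume
  double f0[3];
  double phi;
  double a0, af, b0, bf, K, klog;
  double alv, arv;
};

// local residual: 12 u-rows then 4 p-rows. Returns false if J <= 0.
static bool elem_residual(const ElemCtx& c, const double ue[12],
                          const double pe[4], double r[16]) {
  double F[9] = {1, 0, 0, 0, 1, 0, 0, 0, 1};  // column-major F[i + 3*j]
  for (int a = 0; a < 4; ++a)
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j)
        F[i + 3 * j] += ue[a * 3 + i] * c.G[a * 3 + j];
  double J = det3(F);
  if (!(J > 0)) return false;
  double FinvT[9];
  invT3(F, J, FinvT);
  double I1 = 0;
  for (int i = 0; i < 9; ++i) I1 += F[i] * F[i];
  double Jm23 = std::pow(J, -2.0 / 3.0);
  double Ibar1 = Jm23 * I1;
  double ci = c.a0 * std::exp(c.b0 * (Ibar1 - 3.0)) * Jm23;
  double P[9];
  for (int i = 0; i < 9; ++i) P[i] = ci * (F[i] - (I1 / 3.0) * FinvT[i]);
  // fibre tension term
  double f[3] = {0, 0, 0};
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) f[i] += F[i + 3 * j] * c.f0[j];
  double If = f[0] * f[0] + f[1] * f[1] + f[2] * f[2];
  if (If > 1.0 && c.af > 0) {
    double e, de;
    pospart_smooth(If - 1.0, e, de);
    double cf = 2.0 * c.af * e * de * std::exp(c.bf * e * e);
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j) P[i + 3 * j] += cf * f[i] * c.f0[j];
  }
  // volumetric
  double pbar = 0.25 * (pe[0] + pe[1] + pe[2] + pe[3]);
  for (int i = 0; i < 9; ++i) P[i] += pbar * J * FinvT[i];
  // active
  double amp = c.alv * c.phi + c.arv * (1.0 - c.phi);
  if (amp != 0.0) {
    double ex, dex;
    pospart_smooth(If - 0.8, ex, dex);
    double g = ex > 0 ? std::tanh(2.0 * ex) : 0.0;
    if (g != 0.0) {
      for (int i = 0; i < 3; ++i)
        for (int j = 0; j < 3; ++j)
          P[i + 3 * j] += amp * g * (f[i] * c.f0[j] + F[i + 3 * j] / 3.0);
    }
  }
  for (int a = 0; a < 4; ++a)
    for (int i = 0; i < 3; ++i) {
      double s = 0;
      for (int j = 0; j < 3; ++j) s += P[i + 3 * j] * c.G[a * 3 + j];
      r[a * 3 + i] = c.V * s;
    }
  // pressure equation rows: V/4 K[(J-1) + k ln J] - (M p)_a, exact P1 mass
  double bulk = c.K * ((J - 1.0) + c.klog * std::log(J));
  double psum = pe[0] + pe[1] + pe[2] + pe[3];
  for (int a = 0; a < 4; ++a)
    r[12 + a] = 0.25 * c.V * bulk - c.V / 20.0 * (psum + pe[a]);
  return true;
}

// active residual at unit activation (separately for LV and RV label parts)
static void elem_active_unit(const ElemCtx& c, const double ue[12],
                             double rlv[12], double rrv[12]) {
  double F[9] = {1, 0, 0, 0, 1, 0, 0, 0, 1};
  for (int a = 0; a < 4; ++a)
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j)
        F[i + 3 * j] += ue[a * 3 + i] * c.G[a * 3 + j];
  double f[3] = {0, 0, 0};
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) f[i] += F[i + 3 * j] * c.f0[j];
  double If = f[0] * f[0] + f[1] * f[1] + f[2] * f[2];
  double ex, dex;
  pospart_smooth(If - 0.8, ex, dex);
  double g = ex > 0 ? std::tanh(2.0 * ex) : 0.0;
  double Pa[9];
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j)
      Pa[i + 3 * j] = g * (f[i] * c.f0[j] + F[i + 3 * j] / 3.0);
  for (int a = 0; a < 4; ++a)
    for (int i = 0; i < 3; ++i) {
      double s = 0;
      for (int j = 0; j < 3; ++j) s += Pa[i + 3 * j] * c.G[a * 3 + j];
      rlv[a * 3 + i] = c.V * c.phi * s;
      rrv[a * 3 + i] = c.V * (1.0 - c.phi) * s;
    }
}

// [[Rcpp::export]]
List cpp_volume_assemble(NumericMatrix nodes, IntegerMatrix elems,
                         NumericVector u, NumericVector p,
                         NumericMatrix f0, NumericVector phi_e,
                         NumericVector params, double alpha_lv,
                         double alpha_rv, bool want_jac) {
  const int M = elems.nrow(), N = nodes.nrow();
  NumericVector r_u(3 * N), r_p(N), da_lv(3 * N), da_rv(3 * N);
  std::vector<int> ti, tj;
  std::vector<double> tx;
  if (want_jac) { ti.reserve(M * 256); tj.reserve(M * 256); tx.reserve(M * 256); }
  bool bad = false;
  for (int el = 0; el < M; ++el) {
    ElemCtx c;
    int nd[4];
    for (int a = 0; a < 4; ++a) nd[a] = elems(el, a) - 1;
    // shape gradients from edge matrix inverse
    double e[9];
    for (int a = 1; a < 4; ++a)
      for (int i = 0; i < 3; ++i)
        e[i + 3 * (a - 1)] = nodes(nd[a], i) - nodes(nd[0], i);
    double J6 = det3(e);
    c.V = J6 / 6.0;
    double einvT[9];
    invT3(e, J6, einvT);  // rows of inv(e) are einvT columns
    for (int a = 1; a < 4; ++a)
      for (int j = 0; j < 3; ++j) c.G[a * 3 + j] = einvT[j + 3 * (a - 1)];
    for (int j = 0; j < 3; ++j)
      c.G[j] = -(c.G[3 + j] + c.G[6 + j] + c.G[9 + j]);
    for (int j = 0; j < 3; ++j) c.f0[j] = f0(el, j);
    c.phi = phi_e[el];
    c.a0 = params[0]; c.af = params[1]; c.b0 = params[2]; c.bf = params[3];
    c.K = params[4]; c.klog = params[5];
    c.alv = alpha_lv; c.arv = alpha_rv;
    double ue[12], pe[4];
    for (int a = 0; a < 4; ++a) {
      for (int i = 0; i < 3; ++i) ue[a * 3 + i] = u[3 * nd[a] + i];
      pe[a] = p[nd[a]];
    }
    double r0[16];
    if (!elem_residual(c, ue, pe, r0)) { bad = true; continue; }
    for (int a = 0; a < 4; ++a) {
      for (int i = 0; i < 3; ++i) r_u[3 * nd[a] + i] += r0[a * 3 + i];
      r_p[nd[a]] += r0[12 + a];
    }
    double alv[12], arv[12];
    elem_active_unit(c, ue, alv, arv);
    for (int a = 0; a < 4; ++a)
      for (int i = 0; i < 3; ++i) {
        da_lv[3 * nd[a] + i] += alv[a * 3 + i];
        da_rv[3 * nd[a] + i] += arv[a * 3 + i];
      }
    if (want_jac) {
      int gidx[16];
      for (int a = 0; a < 4; ++a) {
        for (int i = 0; i < 3; ++i) gidx[a * 3 + i] = 3 * nd[a] + i + 1;
        gidx[12 + a] = 3 * N + nd[a] + 1;
      }
      double x[16], rp[16], rm[16];
      for (int q = 0; q < 12; ++q) x[q] = ue[q];
      for (int q = 0; q < 4; ++q) x[12 + q] = pe[q];
      for (int col = 0; col < 16; ++col) {
        double h = 1e-6 * (1.0 + std::fabs(x[col]));
        double save = x[col];
        x[col] = save + h;
        bool ok1 = elem_residual(c, x, x + 12, rp);
        x[col] = save - h;
        bool ok2 = elem_residual(c, x, x + 12, rm);
        x[col] = save;
        if (!ok1 || !ok2) { bad = true; continue; }
        for (int row = 0; row < 16; ++row) {
          double v = (rp[row] - rm[row]) / (2 * h);
          if (v != 0.0) {
            ti.push_back(gidx[row]);
            tj.push_back(gidx[col]);
            tx.push_back(v);
          }
        }
      }
    }
  }
  return List::create(_["r_u"] = r_u, _["r_p"] = r_p,
                      _["da_lv"] = da_lv, _["da_rv"] = da_rv,
                      _["i"] = wrap(ti), _["j"] = wrap(tj), _["x"] = wrap(tx),
                      _["bad"] = bad);
}

// follower pressure load on endocardial facets: residual P * Adef/3 at each
// facet node (Adef = deformed tissue-outward area vector)
static void facet_pressure_residual(const double X[9], const double uf[9],
                                    double P, double r[9]) {
  double x[9];
  for (int q = 0; q < 9; ++q) x[q] = X[q] + uf[q];
  double u1[3], u2[3], A[3];
  for (int i = 0; i < 3; ++i) {
    u1[i] = x[3 + i] - x[i];
    u2[i] = x[6 + i] - x[i];
  }
  A[0] = 0.5 * (u1[1] * u2[2] - u1[2] * u2[1]);
  A[1] = 0.5 * (u1[2] * u2[0] - u1[0] * u2[2]);
  A[2] = 0.5 * (u1[0] * u2[1] - u1[1] * u2[0]);
  for (int a = 0; a < 3; ++a)
    for (int i = 0; i < 3; ++i) r[a * 3 + i] = P * A[i] / 3.0;
}

// [[Rcpp::export]]
List cpp_pressure_load(NumericMatrix nodes, IntegerMatrix facets,
                       NumericVector u, double P, bool want_jac) {
  const int B = facets.nrow(), N = nodes.nrow();
  NumericVector r_u(3 * N), unit(3 * N);
  std::vector<int> ti, tj;
  std::vector<double> tx;
  for (int fct = 0; fct < B; ++fct) {
    int nd[3];
    double X[9], uf[9];
    for (int a = 0; a < 3; ++a) {
      nd[a] = facets(fct, a) - 1;
      for (int i = 0; i < 3; ++i) {
        X[a * 3 + i] = nodes(nd[a], i);
        uf[a * 3 + i] = u[3 * nd[a] + i];
      }
    }
    double r0[9];
    facet_pressure_residual(X, uf, P, r0);
    for (int a = 0; a < 3; ++a)
      for (int i = 0; i < 3; ++i) r_u[3 * nd[a] + i] += r0[a * 3 + i];
    facet_pressure_residual(X, uf, 1.0, r0);
    for (int a = 0; a < 3; ++a)
      for (int i = 0; i < 3; ++i) unit[3 * nd[a] + i] += r0[a * 3 + i];
    if (want_jac && P != 0.0) {
      double rp[9], rm[9];
      for (int col = 0; col < 9; ++col) {
        double h = 1e-6 * (1.0 + std::fabs(uf[col]));
        double save = uf[col];
        uf[col] = save + h;
        facet_pressure_residual(X, uf, P, rp);
        uf[col] = save - h;
        facet_pressure_residual(X, uf, P, rm);
        uf[col] = save;
        for (int row = 0; row < 9; ++row) {
          double v = (rp[row] - rm[row]) / (2 * h);
          if (v != 0.0) {
            ti.push_back(3 * nd[row / 3] + row % 3 + 1);
            tj.push_back(3 * nd[col / 3] + col % 3 + 1);
            tx.push_back(v);
          }
        }
      }
    }
  }
  return List::create(_["r_u"] = r_u, _["unit"] = unit,
                      _["i"] = wrap(ti), _["j"] = wrap(tj), _["x"] = wrap(tx));
}

// valve-annulus surface stress: integrate P_valve : grad0 w over the
// reference facet area using the adjacent tet's P1 gradients
struct ValveCtx {
  double G[12];
  double Aref;
  double f0k[3];
  double c1, c2;
};

static void valve_residual(const ValveCtx& c, const double ue[12], double r[12]) {
  double F[9] = {1, 0, 0, 0, 1, 0, 0, 0, 1};
  for (int a = 0; a < 4; ++a)
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j)
        F[i + 3 * j] += ue[a * 3 + i] * c.G[a * 3 + j];
  double fk[3] = {0, 0, 0};
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) fk[i] += F[i + 3 * j] * c.f0k[j];
  double Ifk = fk[0] * fk[0] + fk[1] * fk[1] + fk[2] * fk[2];
  double coef = c.c1 * (std::exp(c.c2 * (Ifk - 1.0)) - 1.0);
  for (int a = 0; a < 4; ++a)
    for (int i = 0; i < 3; ++i) {
      double s = 0;
      for (int j = 0; j < 3; ++j) s += fk[i] * c.f0k[j] * c.G[a * 3 + j];
      r[a * 3 + i] = c.Aref * coef * s;
    }
}

// [[Rcpp::export]]
List cpp_valve_assemble(NumericMatrix nodes, IntegerMatrix facets,
                        IntegerMatrix ftets, NumericVector u,
                        NumericMatrix f0k, double c1, double c2,
                        bool want_jac) {
  const int B = facets.nrow(), N = nodes.nrow();
  NumericVector r_u(3 * N);
  std::vector<int> ti, tj;
  std::vector<double> tx;
  for (int fct = 0; fct < B; ++fct) {
    ValveCtx c;
    int nd[4];
    for (int a = 0; a < 4; ++a) nd[a] = ftets(fct, a) - 1;
    double e[9];
    for (int a = 1; a < 4; ++a)
      for (int i = 0; i < 3; ++i)
        e[i + 3 * (a - 1)] = nodes(nd[a], i) - nodes(nd[0], i);
    double J6 = det3(e);
    double einvT[9];
    invT3(e, J6, einvT);
    for (int a = 1; a < 4; ++a)
      for (int j = 0; j < 3; ++j) c.G[a * 3 + j] = einvT[j + 3 * (a - 1)];
    for (int j = 0; j < 3; ++j)
      c.G[j] = -(c.G[3 + j] + c.G[6 + j] + c.G[9 + j]);
    // reference facet area
    int fa = facets(fct, 0) - 1, fb = facets(fct, 1) - 1, fc2 = facets(fct, 2) - 1;
    double v1[3], v2[3];
    for (int i = 0; i < 3; ++i) {
      v1[i] = nodes(fb, i) - nodes(fa, i);
      v2[i] = nodes(fc2, i) - nodes(fa, i);
    }
    double Ax = v1[1] * v2[2] - v1[2] * v2[1];
    double Ay = v1[2] * v2[0] - v1[0] * v2[2];
    double Az = v1[0] * v2[1] - v1[1] * v2[0];
    c.Aref = 0.5 * std::sqrt(Ax * Ax + Ay * Ay + Az * Az);
    for (int j = 0; j < 3; ++j) c.f0k[j] = f0k(fct, j);
    c.c1 = c1; c.c2 = c2;
    double ue[12];
    for (int a = 0; a < 4; ++a)
      for (int i = 0; i < 3; ++i) ue[a * 3 + i] = u[3 * nd[a] + i];
    double r0[12];
    valve_residual(c, ue, r0);
    for (int a = 0; a < 4; ++a)
      for (int i = 0; i < 3; ++i) r_u[3 * nd[a] + i] += r0[a * 3 + i];
    if (want_jac) {
      double rp[12], rm[12];
      for (int col = 0; col < 12; ++col) {
        double h = 1e-6 * (1.0 + std::fabs(ue[col]));
        double save = ue[col];
        ue[col] = save + h;
        valve_residual(c, ue, rp);
        ue[col] = save - h;
        valve_residual(c, ue, rm);
        ue[col] = save;
        for (int row = 0; row < 12; ++row) {
          double v = (rp[row] - rm[row]) / (2 * h);
          if (v != 0.0) {
            ti.push_back(3 * nd[row / 3] + row % 3 + 1);
            tj.push_back(3 * nd[col / 3] + col % 3 + 1);
            tx.push_back(v);
          }
        }
      }
    }
  }
  return List::create(_["r_u"] = r_u,
                      _["i"] = wrap(ti), _["j"] = wrap(tj), _["x"] = wrap(tx));
}

// truncated cavity volume from the (open) endocardial surface:
// V = sum_f -1/2 ((I - n n^T) xbar) . Adef ; Adef tissue-outward
static double facet_cavity_vol(const double X[9], const double uf[9],
                               const double n[3]) {
  double x[9];
  for (int q = 0; q < 9; ++q) x[q] = X[q] + uf[q];
  double u1[3], u2[3], A[3], cb[3];
  for (int i = 0; i < 3; ++i) {
    u1[i] = x[3 + i] - x[i];
    u2[i] = x[6 + i] - x[i];
    cb[i] = (x[i] + x[3 + i] + x[6 + i]) / 3.0;
  }
  A[0] = 0.5 * (u1[1] * u2[2] - u1[2] * u2[1]);
  A[1] = 0.5 * (u1[2] * u2[0] - u1[0] * u2[2]);
  A[2] = 0.5 * (u1[0] * u2[1] - u1[1] * u2[0]);
  double cn = cb[0] * n[0] + cb[1] * n[1] + cb[2] * n[2];
  double proj[3];
  for (int i = 0; i < 3; ++i) proj[i] = cb[i] - cn * n[i];
  return -0.5 * (proj[0] * A[0] + proj[1] * A[1] + proj[2] * A[2]);
}

// [[Rcpp::export]]
List cpp_cavity_volume(NumericMatrix nodes, IntegerMatrix facets,
                       NumericVector u, NumericVector nvec, bool want_grad) {
  const int B = facets.nrow(), N = nodes.nrow();
  double V = 0;
  NumericVector grad(want_grad ? 3 * N : 0);
  double n[3] = {nvec[0], nvec[1], nvec[2]};
  for (int fct = 0; fct < B; ++fct) {
    int nd[3];
    double X[9], uf[9];
    for (int a = 0; a < 3; ++a) {
      nd[a] = facets(fct, a) - 1;
      for (int i = 0; i < 3; ++i) {
        X[a * 3 + i] = nodes(nd[a], i);
        uf[a * 3 + i] = u[3 * nd[a] + i];
      }
    }
    V += facet_cavity_vol(X, uf, n);
    if (want_grad) {
      for (int col = 0; col < 9; ++col) {
        double h = 1e-6 * (1.0 + std::fabs(uf[col]));
        double save = uf[col];
        uf[col] = save + h;
        double vp = facet_cavity_vol(X, uf, n);
        uf[col] = save - h;
        double vm = facet_cavity_vol(X, uf, n);
        uf[col] = save;
        grad[3 * nd[col / 3] + col % 3] += (vp - vm) / (2 * h);
      }
    }
  }
  return List::create(_["V"] = V, _["grad"] = grad);
}

// minimum distance from each point to a triangle soup (Ericson's
// closest-point-on-triangle), brute force over triangles
static double pt_tri_dist2(const double p[3], const double a[3],
                           const double b[3], const double c[3]) {
  double ab[3], ac[3], ap[3];
  for (int i = 0; i < 3; ++i) {
    ab[i] = b[i] - a[i]; ac[i] = c[i] - a[i]; ap[i] = p[i] - a[i];
  }
  double d1 = ab[0] * ap[0] + ab[1] * ap[1] + ab[2] * ap[2];
  double d2 = ac[0] * ap[0] + ac[1] * ap[1] + ac[2] * ap[2];
  double q[3];
  if (d1 <= 0 && d2 <= 0) { for (int i = 0; i < 3; ++i) q[i] = a[i]; goto done; }
  {
    double bp[3];
    for (int i = 0; i < 3; ++i) bp[i] = p[i] - b[i];
    double d3 = ab[0] * bp[0] + ab[1] * bp[1] + ab[2] * bp[2];
    double d4 = ac[0] * bp[0] + ac[1] * bp[1] + ac[2] * bp[2];
    if (d3 >= 0 && d4 <= d3) { for (int i = 0; i < 3; ++i) q[i] = b[i]; goto done; }
    double vc = d1 * d4 - d3 * d2;
    if (vc <= 0 && d1 >= 0 && d3 <= 0) {
      double v = d1 / (d1 - d3);
      for (int i = 0; i < 3; ++i) q[i] = a[i] + v * ab[i];
      goto done;
    }
    double cp[3];
    for (int i = 0; i < 3; ++i) cp[i] = p[i] - c[i];
    double d5 = ab[0] * cp[0] + ab[1] * cp[1] + ab[2] * cp[2];
    double d6 = ac[0] * cp[0] + ac[1] * cp[1] + ac[2] * cp[2];
    if (d6 >= 0 && d5 <= d6) { for (int i = 0; i < 3; ++i) q[i] = c[i]; goto done; }
    double vb = d5 * d2 - d1 * d6;
    if (vb <= 0 && d2 >= 0 && d6 <= 0) {
      double w = d2 / (d2 - d6);
      for (int i = 0; i < 3; ++i) q[i] = a[i] + w * ac[i];
      goto done;
    }
    double va = d3 * d6 - d5 * d4;
    if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
      double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
      for (int i = 0; i < 3; ++i) q[i] = b[i] + w * (c[i] - b[i]);
      goto done;
    }
    {
      double denom = 1.0 / (va + vb + vc);
      double v = vb * denom, w = vc * denom;
      for (int i = 0; i < 3; ++i) q[i] = a[i] + ab[i] * v + ac[i] * w;
    }
  }
done:
  double dx = p[0] - q[0], dy = p[1] - q[1], dz = p[2] - q[2];
  return dx * dx + dy * dy + dz * dz;
}

// [[Rcpp::export]]
NumericVector cpp_min_dist_to_tris(NumericMatrix pts, NumericMatrix ta,
                                   NumericMatrix tb, NumericMatrix tc) {
  const int np = pts.nrow(), nt = ta.nrow();
  NumericVector out(np);
  for (int ip = 0; ip < np; ++ip) {
    double p[3] = {pts(ip, 0), pts(ip, 1), pts(ip, 2)};
    double best = R_PosInf;
    for (int it = 0; it < nt; ++it) {
      double a[3] = {ta(it, 0), ta(it, 1), ta(it, 2)};
      double b[3] = {tb(it, 0), tb(it, 1), tb(it, 2)};
      double c[3] = {tc(it, 0), tc(it, 1), tc(it, 2)};
      double d2 = pt_tri_dist2(p, a, b, c);
      if (d2 < best) best = d2;
    }
    out[ip] = std::sqrt(best);
  }
  return out;
}

// 4-connected component labelling of a binary mask (flood fill)
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<int> stack;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j)) continue;
      ++next;
      stack.push_back(i + nr * j);
      while (!stack.empty()) {
        int q = stack.back();
        stack.pop_back();
        int qi = q % nr, qj = q / nr;
        if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
        if (!mask(qi, qj) || lab(qi, qj)) continue;
        lab(qi, qj) = next;
        if (qi > 0) stack.push_back(q - 1);
        if (qi < nr - 1) stack.push_back(q + 1);
        if (qj > 0) stack.push_back(q - nr);
        if (qj < nc - 1) stack.push_back(q + nr);
      }
    }
  return lab;
}
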