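// Discrete shell mechanics for the growing canvas.
//
// The canvas carries per-triangle rest metrics (edge-pair Gram tensors) for
// its two surfaces A and B.  The elastic energy has
//  * a membrane part: for each triangle and each surface, a plane-stress
//    St-Venant--Kirchhoff density on the difference between the realised
//    Gram tensor and that surface's rest Gram, integrated over the rest
//    area and the layer thickness h/2;
//  * a bending part: for each interior edge (hinge) a quadratic penalty
//    k_b (theta - theta0)^2 on the signed dihedral angle, with the
//    spontaneous angle theta0 derived (in R) from the A/B rest differential,
//    so differential surface growth induces spontaneous curvature.
// Quasi-static equilibrium is found by Polak-Ribiere conjugate gradients
// with Armijo backtracking (monotone in energy).  Gradients are assembled
// from local central finite differences per element, which is exact to
// O(eps^2) and keeps the energy definition the single source of truth.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

struct Mesh {
  int nv, nt, nh;
  const double *x;            // 3*nv, column-major (x,y,z per vertex rows in R)
  std::vector<int> tri;       // 3*nt, 0-based
  std::vector<double> restA;  // 3*nt: g11,g12,g22
  std::vector<double> restB;
  std::vector<double> areaA;  // rest areas per triangle per surface
  std::vector<double> areaB;
  std::vector<double> htri;   // thickness per triangle
  std::vector<int> hinge;     // 4*nh: i,j,k,l (0-based)
  std::vector<double> theta0;
  std::vector<double> kb;
  double lambda, mu;
};

static inline void getv(const std::vector<double>& X, int nv, int i, double* out) {
  out[0] = X[i]; out[1] = X[i + nv]; out[2] = X[i + 2 * nv];
}

static inline double tri_energy(const Mesh& m, const std::vector<double>& X, int t) {
  int nv = m.nv;
  int i = m.tri[t], j = m.tri[t + m.nt], k = m.tri[t + 2 * m.nt];
  double p1[3], p2[3], p3[3];
  getv(X, nv, i, p1); getv(X, nv, j, p2); getv(X, nv, k, p3);
  double d1[3] = {p2[0] - p1[0], p2[1] - p1[1], p2[2] - p1[2]};
  double d2[3] = {p3[0] - p1[0], p3[1] - p1[1], p3[2] - p1[2]};
  double c11 = d1[0] * d1[0] + d1[1] * d1[1] + d1[2] * d1[2];
  double c12 = d1[0] * d2[0] + d1[1] * d2[1] + d1[2] * d2[2];
  double c22 = d2[0] * d2[0] + d2[1] * d2[1] + d2[2] * d2[2];
  double e = 0.0;
  for (int s = 0; s < 2; ++s) {
    const double* g = (s == 0) ? &m.restA[3 * t] : &m.restB[3 * t];
    double a0 = (s == 0) ? m.areaA[t] : m.areaB[t];
    double det = g[0] * g[2] - g[1] * g[1];
    if (det <= 0) continue;
    // E = (C - G)/2 (covariant), Ginv * E mixed tensor
    double e11 = 0.5 * (c11 - g[0]);
    double e12 = 0.5 * (c12 - g[1]);
    double e22 = 0.5 * (c22 - g[2]);
    double i11 = g[2] / det, i12 = -g[1] / det, i22 = g[0] / det;
    // S = Ginv E
    double s11 = i11 * e11 + i12 * e12;
    double s12 = i11 * e12 + i12 * e22;
    double s21 = i12 * e11 + i22 * e12;
    double s22 = i12 * e12 + i22 * e22;
    double tr = s11 + s22;
    double tr2 = s11 * s11 + 2.0 * s12 * s21 + s22 * s22;
    double W = 0.5 * m.lambda * tr * tr + m.mu * tr2;
    e += a0 * 0.5 * m.htri[t] * W;  // each surface carries half the thickness
  }
  return e;
}

static inline void cross(const double* a, const double* b, double* out) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}

static inline double dot(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}

// signed dihedral angle at hinge h: positive when the two faces fold
// towards their normals' side (normals from consistent winding)
static inline double hinge_angle(const Mesh& m, const std::vector<double>& X, int h) {
  int nv = m.nv;
  int i = m.hinge[h], j = m.hinge[h + m.nh];
  int k = m.hinge[h + 2 * m.nh], l = m.hinge[h + 3 * m.nh];
  double xi[3], xj[3], xk[3], xl[3];
  getv(X, nv, i, xi); getv(X, nv, j, xj); getv(X, nv, k, xk); getv(X, nv, l, xl);
  double e[3] = {xj[0] - xi[0], xj[1] - xi[1], xj[2] - xi[2]};
  double u1[3] = {xk[0] - xi[0], xk[1] - xi[1], xk[2] - xi[2]};
  double u2[3] = {xl[0] - xi[0], xl[1] - xi[1], xl[2] - xi[2]};
  double n1[3], n2[3];
  cross(e, u1, n1);   // normal of triangle (i, j, k) flipped sign vs winding?
  cross(u2, e, n2);   // normal of triangle (i, l, j)
  double cx[3];
  cross(n1, n2, cx);
  double el = std::sqrt(dot(e, e));
  if (el < 1e-300) return 0.0;
  double s = dot(cx, e) / el;
  double c = dot(n1, n2);
  return std::atan2(s, c);
}

static inline double hinge_energy(const Mesh& m, const std::vector<double>& X, int h) {
  double th = hinge_angle(m, X, h);
  double d = th - m.theta0[h];
  return m.kb[h] * d * d;
}

static double total_energy(const Mesh& m, const std::vector<double>& X) {
  double e = 0.0;
  for (int t = 0; t < m.nt; ++t) e += tri_energy(m, X, t);
  for (int h = 0; h < m.nh; ++h) e += hinge_energy(m, X, h);
  return e;
}

// accumulate gradient by local central differences
static void gradient(const Mesh& m, std::vector<double>& X,
                     std::vector<double>& g, double eps) {
  std::fill(g.begin(), g.end(), 0.0);
  int nv = m.nv;
  for (int t = 0; t < m.nt; ++t) {
    int vid[3] = {m.tri[t], m.tri[t + m.nt], m.tri[t + 2 * m.nt]};
    for (int a = 0; a < 3; ++a) {
      for (int c = 0; c < 3; ++c) {
        int idx = vid[a] + c * nv;
        double old = X[idx];
        X[idx] = old + eps;
        double ep = tri_energy(m, X, t);
        X[idx] = old - eps;
        double em = tri_energy(m, X, t);
        X[idx] = old;
        g[idx] += (ep - em) / (2.0 * eps);
      }
    }
  }
  for (int h = 0; h < m.nh; ++h) {
    int vid[4] = {m.hinge[h], m.hinge[h + m.nh],
                  m.hinge[h + 2 * m.nh], m.hinge[h + 3 * m.nh]};
    for (int a = 0; a < 4; ++a) {
      for (int c = 0; c < 3; ++c) {
        int idx = vid[a] + c * nv;
        double old = X[idx];
        X[idx] = old + eps;
        double ep = hinge_energy(m, X, h);
        X[idx] = old - eps;
        double em = hinge_energy(m, X, h);
        X[idx] = old;
        g[idx] += (ep - em) / (2.0 * eps);
      }
    }
  }
}

static Mesh build_mesh(const NumericMatrix& verts, const IntegerMatrix& tris,
                       const NumericMatrix& restA, const NumericMatrix& restB,
                       const NumericVector& htri, const IntegerMatrix& hinges,
                       const NumericVector& theta0, const NumericVector& kb,
                       double nu) {
  Mesh m;
  m.nv = verts.nrow();
  m.nt = tris.nrow();
  m.nh = hinges.nrow();
  m.tri.resize(3 * m.nt);
  m.restA.resize(3 * m.nt);
  m.restB.resize(3 * m.nt);
  m.areaA.resize(m.nt);
  m.areaB.resize(m.nt);
  m.htri.resize(m.nt);
  for (int t = 0; t < m.nt; ++t) {
    for (int c = 0; c < 3; ++c) {
      m.tri[t + c * m.nt] = tris(t, c) - 1;
      m.restA[3 * t + c] = restA(t, c);
      m.restB[3 * t + c] = restB(t, c);
    }
    double dA = restA(t, 0) * restA(t, 2) - restA(t, 1) * restA(t, 1);
    double dB = restB(t, 0) * restB(t, 2) - restB(t, 1) * restB(t, 1);
    m.areaA[t] = 0.5 * std::sqrt(std::max(dA, 0.0));
    m.areaB[t] = 0.5 * std::sqrt(std::max(dB, 0.0));
    m.htri[t] = htri[t];
  }
  m.hinge.resize(4 * std::max(m.nh, 1));
  m.theta0.resize(std::max(m.nh, 1));
  m.kb.resize(std::max(m.nh, 1));
  for (int h = 0; h < m.nh; ++h) {
    for (int c = 0; c < 4; ++c) m.hinge[h + c * m.nh] = hinges(h, c) - 1;
    m.theta0[h] = theta0[h];
    m.kb[h] = kb[h];
  }
  m.mu = 1.0 / (2.0 * (1.0 + nu));
  m.lambda = nu / (1.0 - nu * nu);
  return m;
}

static std::vector<double> flatten(const NumericMatrix& verts) {
  int nv = verts.nrow();
  std::vector<double> X(3 * nv);
  for (int i = 0; i < nv; ++i)
    for (int c = 0; c < 3; ++c) X[i + c * nv] = verts(i, c);
  return X;
}

// [[Rcpp::export(name = ".shell_energy")]]
double shell_energy_cpp(NumericMatrix verts, IntegerMatrix tris,
                        NumericMatrix restA, NumericMatrix restB,
                        NumericVector htri, IntegerMatrix hinges,
                        NumericVector theta0, NumericVector kb, double nu) {
  Mesh m = build_mesh(verts, tris, restA, restB, htri, hinges, theta0, kb, nu);
  std::vector<double> X = flatten(verts);
  return total_energy(m, X);
}

// [[Rcpp::export(name = ".shell_gradient")]]
NumericMatrix shell_gradient_cpp(NumericMatrix verts, IntegerMatrix tris,
                                 NumericMatrix restA, NumericMatrix restB,
                                 NumericVector htri, IntegerMatrix hinges,
                                 NumericVector theta0, NumericVector kb,
                                 double nu, double eps) {
  Mesh m = build_mesh(verts, tris, restA, restB, htri, hinges, theta0, kb, nu);
  std::vector<double> X = flatten(verts);
  std::vector<double> g(3 * m.nv);
  gradient(m, X, g, eps);
  NumericMatrix out(m.nv, 3);
  for (int i = 0; i < m.nv; ++i)
    for (int c = 0; c < 3; ++c) out(i, c) = g[i + c * m.nv];
  return out;
}

// [[Rcpp::export(name = ".shell_hinge_angles")]]
NumericVector shell_hinge_angles_cpp(NumericMatrix verts, IntegerMatrix tris,
                                     NumericMatrix restA, NumericMatrix restB,
                                     NumericVector htri, IntegerMatrix hinges,
                                     NumericVector theta0, NumericVector kb,
                                     double nu) {
  Mesh m = build_mesh(verts, tris, restA, restB, htri, hinges, theta0, kb, nu);
  std::vector<double> X = flatten(verts);
  NumericVector out(m.nh);
  for (int h = 0; h < m.nh; ++h) out[h] = hinge_angle(m, X, h);
  return out;
}

// [[Rcpp::export(name = ".shell_relax")]]
List shell_relax_cpp(NumericMatrix verts, IntegerMatrix tris,
                     NumericMatrix restA, NumericMatrix restB,
                     NumericVector htri, IntegerMatrix hinges,
                     NumericVector theta0, NumericVector kb,
                     double nu, double tol, int max_iter, double eps) {
  Mesh m = build_mesh(verts, tris, restA, restB, htri, hinges, theta0, kb, nu);
  std::vector<double> X = flatten(verts);
  int n = 3 * m.nv;
  std::vector<double> g(n), gprev(n), dir(n), Xtrial(n);
  double E = total_energy(m, X);
  double E0 = std::max(std::abs(E), 1e-300);
  gradient(m, X, g, eps);
  for (int i = 0; i < n; ++i) dir[i] = -g[i];
  int iter = 0, stall = 0;
  bool converged = false;
  double step = 1.0;
  std::vector<double> trace;
  trace.push_back(E);
  while (iter < max_iter) {
    ++iter;
    double gd = 0.0, gg = 0.0;
    for (int i = 0; i < n; ++i) { gd += g[i] * dir[i]; gg += g[i] * g[i]; }
    if (std::sqrt(gg) < 1e-14 * (1.0 + E0)) { converged = true; break; }
    if (gd >= 0) {  // not a descent direction: restart with steepest descent
      for (int i = 0; i < n; ++i) dir[i] = -g[i];
      gd = -gg;
    }
    // Armijo backtracking from an adaptive initial step
    double t = step;
    double Enew = E;
    bool ok = false;
    for (int ls = 0; ls < 60; ++ls) {
      for (int i = 0; i < n; ++i) Xtrial[i] = X[i] + t * dir[i];
      Enew = total_energy(m, Xtrial);
      if (Enew <= E + 1e-4 * t * gd) { ok = true; break; }
      t *= 0.5;
    }
    if (!ok) break;  // cannot decrease: converged to tolerance of FD noise
    X.swap(Xtrial);
    double dE = E - Enew;
    E = Enew;
    trace.push_back(E);
    step = std::min(std::max(t * 2.0, 1e-8), 1e6);
    gprev.swap(g);
    gradient(m, X, g, eps);
    // Polak-Ribiere beta
    double num = 0.0, den = 0.0;
    for (int i = 0; i < n; ++i) {
      num += g[i] * (g[i] - gprev[i]);
      den += gprev[i] * gprev[i];
    }
    double beta = (den > 0) ? std::max(num / den, 0.0) : 0.0;
    for (int i = 0; i < n; ++i) dir[i] = -g[i] + beta * dir[i];
    if (dE < tol * std::max(std::abs(E), 1e-12)) {
      if (++stall >= 3) { converged = true; break; }
    } else stall = 0;
  }
  NumericMatrix out(m.nv, 3);
  for (int i = 0; i < m.nv; ++i)
    for (int c = 0; c < 3; ++c) out(i, c) = X[i + c * m.nv];
  return List::create(_["vertices"] = out, _["energy"] = E,
                      _["iterations"] = iter, _["converged"] = converged,
                      _["trace"] = NumericVector(trace.begin(), trace.end()));
}
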