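// Element-level finite-element kernels: P1 scalar stiffness (harmonic
// lifting), one implicit-Euler step of the stabilized P1-P1 ALE
// Navier-Stokes system, element gradients, and exact point-to-triangle
// distances. Everything returns 1-based triplets for Matrix::sparseMatrix.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// gradients of the 4 P1 basis functions on one tet; returns volume
static double p1_gradients(const double x[4][3], double g[4][3]) {
  arma::mat33 J;
  for (int c = 0; c < 3; ++c)
    for (int a = 0; a < 3; ++a) J(c, a) = x[a + 1][c] - x[0][c];
  double det = arma::det(J);
  arma::mat33 Jit = arma::inv(J).t();
  for (int a = 1; a < 4; ++a)
    for (int c = 0; c < 3; ++c) g[a][c] = Jit(c, a - 1);
  for (int c = 0; c < 3; ++c) g[0][c] = -(g[1][c] + g[2][c] + g[3][c]);
  return det / 6.0;
}

// [[Rcpp::export(name = ".asm_scalar_stiffness_cpp")]]
List asm_scalar_stiffness_cpp(const NumericMatrix& V, const IntegerMatrix& T,
                              const NumericVector& coef) {
  const int ne = T.nrow();
  std::vector<int> ti; std::vector<int> tj; std::vector<double> tx;
  ti.reserve(16 * ne); tj.reserve(16 * ne); tx.reserve(16 * ne);
  double x[4][3], g[4][3];
  for (int e = 0; e < ne; ++e) {
    int nd[4];
    for (int a = 0; a < 4; ++a) {
      nd[a] = T(e, a) - 1;
      for (int c = 0; c < 3; ++c) x[a][c] = V(nd[a], c);
    }
    double vol = p1_gradients(x, g);
    double k = coef[e] * vol;
    for (int a = 0; a < 4; ++a)
      for (int b = 0; b < 4; ++b) {
        double v = k * (g[a][0] * g[b][0] + g[a][1] * g[b][1] +
                        g[a][2] * g[b][2]);
        ti.push_back(nd[a] + 1); tj.push_back(nd[b] + 1); tx.push_back(v);
      }
  }
  return List::create(_["i"] = wrap(ti), _["j"] = wrap(tj),
                      _["x"] = wrap(tx));
}

// One implicit-Euler step of the SUPG/PSPG/grad-div stabilized P1-P1 ALE
// Navier-Stokes system. Unknown ordering: ux (1..n), uy, uz, p (3n+1..4n).
// uold/uale are n x 3 nodal fields; convection uses w = uold - uale frozen
// within the step (semi-implicit). Dirichlet dofs (dir != 0, value dirval)
// are condensed out: their test rows are skipped and their columns are
// moved to the right-hand side, so the caller solves the free system only.
// [[Rcpp::export(name = ".asm_ns_step_cpp")]]
List asm_ns_step_cpp(const NumericMatrix& V, const IntegerMatrix& T,
                     const NumericMatrix& uold, const NumericMatrix& uale,
                     double rho, double mu, double dt,
                     double ct, double cc, double cv, double gd,
                     const IntegerVector& dir, const NumericVector& dirval) {
  const int ne = T.nrow();
  const int n = V.nrow();
  const double nu = mu / rho;
  std::vector<int> ti; std::vector<int> tj; std::vector<double> tx;
  ti.reserve(256 * (size_t)ne); tj.reserve(256 * (size_t)ne);
  tx.reserve(256 * (size_t)ne);
  NumericVector rhs(4 * n);
  double x[4][3], g[4][3];
  double Ke[16][16], re[16];

  for (int e = 0; e < ne; ++e) {
    int nd[4];
    for (int a = 0; a < 4; ++a) {
      nd[a] = T(e, a) - 1;
      for (int c = 0; c < 3; ++c) x[a][c] = V(nd[a], c);
    }
    double vol = p1_gradients(x, g);
    double w[3] = {0, 0, 0}, uo[4][3];
    for (int a = 0; a < 4; ++a)
      for (int c = 0; c < 3; ++c) {
        uo[a][c] = uold(nd[a], c);
        w[c] += 0.25 * (uold(nd[a], c) - uale(nd[a], c));
      }
    double wn = std::sqrt(w[0] * w[0] + w[1] * w[1] + w[2] * w[2]);
    double h = std::cbrt(6.0 * std::sqrt(2.0) * std::fabs(vol));
    double tau = 1.0 / std::sqrt(std::pow(ct / dt, 2) +
                                 std::pow(cc * wn / h, 2) +
                                 std::pow(cv * nu / (h * h), 2));
    double nuc = gd * (nu + 0.5 * wn * h);
    double wg[4]; // w . grad(phi_a)
    for (int a = 0; a < 4; ++a)
      wg[a] = w[0] * g[a][0] + w[1] * g[a][1] + w[2] * g[a][2];

    for (int a = 0; a < 16; ++a) {
      re[a] = 0;
      for (int b = 0; b < 16; ++b) Ke[a][b] = 0;
    }
    const double v4 = vol / 4.0;

    for (int i = 0; i < 4; ++i) {
      for (int j = 0; j < 4; ++j) {
        double mij = vol / 20.0 * (i == j ? 2.0 : 1.0);
        double gg = g[i][0] * g[j][0] + g[i][1] * g[j][1] +
                    g[i][2] * g[j][2];
        // same-component velocity block
        double diag = rho / dt * mij           // time derivative
                    + rho * wg[j] * v4         // convection
                    + mu * vol * gg            // grad-grad viscous part
                    + tau * rho * wg[i] * (v4 / dt + wg[j] * vol); // SUPG
        for (int c = 0; c < 3; ++c) Ke[4 * c + i][4 * c + j] += diag;
        // cross-component: viscous transpose part + grad-div
        for (int a = 0; a < 3; ++a)
          for (int b = 0; b < 3; ++b)
            Ke[4 * a + i][4 * b + j] +=
                mu * vol * g[i][b] * g[j][a] +
                rho * nuc * vol * g[i][a] * g[j][b];
        // momentum-pressure: Galerkin -(p, div v) + SUPG pressure
        for (int a = 0; a < 3; ++a)
          Ke[4 * a + i][12 + j] +=
              -g[i][a] * v4 + tau * wg[i] * g[j][a] * vol;
        // continuity-velocity: Galerkin (div u, q) + PSPG
        for (int b = 0; b < 3; ++b)
          Ke[12 + i][4 * b + j] +=
              g[j][b] * v4 + tau * g[i][b] * (v4 / dt + wg[j] * vol);
        // PSPG pressure-pressure
        Ke[12 + i][12 + j] += tau / rho * gg * vol;
        // rhs: Galerkin time term with consistent mass
        for (int c = 0; c < 3; ++c)
          re[4 * c + i] += rho / dt * mij * uo[j][c];
      }
      // rhs: SUPG/PSPG time terms
      double su[3] = {0, 0, 0};
      for (int j = 0; j < 4; ++j)
        for (int c = 0; c < 3; ++c) su[c] += uo[j][c];
      for (int c = 0; c < 3; ++c)
        re[4 * c + i] += tau * rho * wg[i] * v4 / dt * su[c];
      double pr = 0;
      for (int b = 0; b < 3; ++b) pr += g[i][b] * su[b];
      re[12 + i] += tau * v4 / dt * pr;
    }

    int gdof[16];
    for (int c = 0; c < 4; ++c)
      for (int a = 0; a < 4; ++a) gdof[4 * c + a] = c * n + nd[a] + 1;
    for (int a = 0; a < 16; ++a) {
      if (dir[gdof[a] - 1]) continue;
      rhs[gdof[a] - 1] += re[a];
      for (int b = 0; b < 16; ++b) {
        if (Ke[a][b] == 0.0) continue;
        if (dir[gdof[b] - 1]) {
          rhs[gdof[a] - 1] -= Ke[a][b] * dirval[gdof[b] - 1];
        } else {
          ti.push_back(gdof[a]); tj.push_back(gdof[b]);
          tx.push_back(Ke[a][b]);
        }
      }
    }
  }
  return List::create(_["i"] = wrap(ti), _["j"] = wrap(tj),
                      _["x"] = wrap(tx), _["rhs"] = rhs);
}

// element-constant gradients of P1 nodal fields; returns ne x (3*ncol)
// matrix with columns (d f1/dx, d f1/dy, d f1/dz, d f2/dx, ...), plus
// element volumes in the attribute-free second list slot.
// [[Rcpp::export(name = ".elem_gradients_cpp")]]
List elem_gradients_cpp(const NumericMatrix& V, const IntegerMatrix& T,
                        const NumericMatrix& field) {
  const int ne = T.nrow();
  const int nc = field.ncol();
  NumericMatrix G(ne, 3 * nc);
  NumericVector vols(ne);
  double x[4][3], g[4][3];
  for (int e = 0; e < ne; ++e) {
    int nd[4];
    for (int a = 0; a < 4; ++a) {
      nd[a] = T(e, a) - 1;
      for (int c = 0; c < 3; ++c) x[a][c] = V(nd[a], c);
    }
    vols[e] = p1_gradients(x, g);
    for (int c = 0; c < nc; ++c)
      for (int k = 0; k < 3; ++k) {
        double s = 0;
        for (int a = 0; a < 4; ++a) s += g[a][k] * field(nd[a], c);
        G(e, 3 * c + k) = s;
      }
  }
  return List::create(_["grad"] = G, _["vol"] = vols);
}

static double clamp01(double t) { return t < 0 ? 0 : (t > 1 ? 1 : t); }

// squared distance from point p to triangle (a,b,c); Ericson's algorithm
static double pt_tri_d2(const double* p, const double* a, const double* b,
                        const double* c) {
  double ab[3], ac[3], ap[3];
  for (int k = 0; k < 3; ++k) {
    ab[k] = b[k] - a[k]; ac[k] = c[k] - a[k]; ap[k] = p[k] - a[k];
  }
  double d1 = ab[0] * ap[0] + ab[1] * ap[1] + ab[2] * ap[2];
  double d2 = ac[0] * ap[0] + ac[1] * ap[1] + ac[2] * ap[2];
  double q[3];
  if (d1 <= 0 && d2 <= 0) {
    for (int k = 0; k < 3; ++k) q[k] = a[k];
  } else {
    double bp[3], cp[3];
    for (int k = 0; k < 3; ++k) { bp[k] = p[k] - b[k]; cp[k] = p[k] - c[k]; }
    double d3 = ab[0] * bp[0] + ab[1] * bp[1] + ab[2] * bp[2];
    double d4 = ac[0] * bp[0] + ac[1] * bp[1] + ac[2] * bp[2];
    double d5 = ab[0] * cp[0] + ab[1] * cp[1] + ab[2] * cp[2];
    double d6 = ac[0] * cp[0] + ac[1] * cp[1] + ac[2] * cp[2];
    if (d3 >= 0 && d4 <= d3) {
      for (int k = 0; k < 3; ++k) q[k] = b[k];
    } else if (d6 >= 0 && d5 <= d6) {
      for (int k = 0; k < 3; ++k) q[k] = c[k];
    } else {
      double vc = d1 * d4 - d3 * d2;
      double vb = d5 * d2 - d1 * d6;
      double va = d3 * d6 - d5 * d4;
      if (vc <= 0 && d1 >= 0 && d3 <= 0) {
        double t = clamp01(d1 / (d1 - d3));
        for (int k = 0; k < 3; ++k) q[k] = a[k] + t * ab[k];
      } else if (vb <= 0 && d2 >= 0 && d6 <= 0) {
        double t = clamp01(d2 / (d2 - d6));
        for (int k = 0; k < 3; ++k) q[k] = a[k] + t * ac[k];
      } else if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
        double t = clamp01((d4 - d3) / ((d4 - d3) + (d5 - d6)));
        for (int k = 0; k < 3; ++k) q[k] = b[k] + t * (c[k] - b[k]);
      } else {
        double den = 1.0 / (va + vb + vc);
        double v = vb * den, w = vc * den;
        for (int k = 0; k < 3; ++k) q[k] = a[k] + ab[k] * v + ac[k] * w;
      }
    }
  }
  double s = 0;
  for (int k = 0; k < 3; ++k) s += (p[k] - q[k]) * (p[k] - q[k]);
  return s;
}

// [[Rcpp::export(name = ".point_tri_dist_cpp")]]
NumericVector point_tri_dist_cpp(const NumericMatrix& P,
                                 const NumericMatrix& V,
                                 const IntegerMatrix& F) {
  const int np = P.nrow(), nf = F.nrow();
  NumericVector out(np);
  std::vector<double> a(3 * nf), b(3 * nf), c(3 * nf);
  for (int f = 0; f < nf; ++f)
    for (int k = 0; k < 3; ++k) {
      a[3 * f + k] = V(F(f, 0) - 1, k);
      b[3 * f + k] = V(F(f, 1) - 1, k);
      c[3 * f + k] = V(F(f, 2) - 1, k);
    }
  for (int i = 0; i < np; ++i) {
    double p[3] = {P(i, 0), P(i, 1), P(i, 2)};
    double best = R_PosInf;
    for (int f = 0; f < nf; ++f) {
      double d2 = pt_tri_d2(p, &a[3 * f], &b[3 * f], &c[3 * f]);
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
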