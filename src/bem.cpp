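// Single-layer boundary-element solver for rigid/beating swimmers.
//
// Representation: disturbance velocity u_d(x) = (1/8pi) \int_S G(x, y) q(y) dS,
// with q the single-layer density scaled by viscosity (units of 1/s when
// lengths are in micrometres).  Constant (BEM0) elements, collocation at
// element centroids.  Self-element integrals use a Duffy-type polar split at
// the collocation point; near-singular neighbours use recursive 4-way
// subdivision; regular elements a 7-point degree-5 Gauss rule.
//
// The mobility problem appends the six rigid-body unknowns (U, Omega) and
// the force/torque balance rows; the pressure-gauge (normal density) null
// vector of the single-layer operator is removed by rank-one deflation.

#include <RcppArmadillo.h>
#include "kernels.h"
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// 7-point degree-5 rule on the unit triangle (barycentric, weights sum to 1)
static const double QW[7] = {0.225,
  0.13239415278850618, 0.13239415278850618, 0.13239415278850618,
  0.12593918054482715, 0.12593918054482715, 0.12593918054482715};
static const double QA[7] = {1.0 / 3.0,
  0.05971587178976982, 0.47014206410511505, 0.47014206410511505,
  0.7974269853530873, 0.10128650732345634, 0.10128650732345634};
static const double QB[7] = {1.0 / 3.0,
  0.47014206410511505, 0.05971587178976982, 0.47014206410511505,
  0.10128650732345634, 0.7974269853530873, 0.10128650732345634};

// 8-point Gauss-Legendre on [0,1]
static const double GL8X[8] = {
  0.019855071751231856, 0.10166676129318664, 0.2372337950418355,
  0.40828267875217505, 0.591717321247825, 0.7627662049581645,
  0.8983332387068134, 0.9801449282487682};
static const double GL8W[8] = {
  0.05061426814518813, 0.11119051722668723, 0.15685332293894363,
  0.18134189168918102, 0.18134189168918102, 0.15685332293894363,
  0.11119051722668723, 0.05061426814518813};

struct Tri {
  double v0[3], v1[3], v2[3], cen[3], nrm[3];
  double area, diam;
};

// accumulate w * G_stokeslet(x, y) into acc[9] (row-major 3x3)
static inline void acc_stokeslet(const double* x, const double* y, double w,
                                 double* acc) {
  double r0 = x[0] - y[0], r1 = x[1] - y[1], r2 = x[2] - y[2];
  double r2sum = r0 * r0 + r1 * r1 + r2 * r2;
  double ir = 1.0 / std::sqrt(r2sum);
  double ir3 = ir / r2sum;
  acc[0] += w * (ir + r0 * r0 * ir3);
  acc[4] += w * (ir + r1 * r1 * ir3);
  acc[8] += w * (ir + r2 * r2 * ir3);
  double g01 = w * r0 * r1 * ir3, g02 = w * r0 * r2 * ir3,
         g12 = w * r1 * r2 * ir3;
  acc[1] += g01; acc[3] += g01;
  acc[2] += g02; acc[6] += g02;
  acc[5] += g12; acc[7] += g12;
}

// accumulate w * Blake image correction (wall x1 = 0, normal index 0)
static inline void acc_blake_image(const double* x, const double* y,
                                   double w, double* acc) {
  double h = y[0];
  double R0 = x[0] + h, R1 = x[1] - y[1], R2 = x[2] - y[2];
  double R[3] = {R0, R1, R2};
  double r2sum = R0 * R0 + R1 * R1 + R2 * R2;
  double iR = 1.0 / std::sqrt(r2sum);
  double iR3 = iR / r2sum;
  double iR5 = iR3 / r2sum;
  double th = 2.0 * h;
  // minus image stokeslet, plus 2 h M_j d/dR_j [h R_i/R^3 - d_i0/R - R_i R_0/R^3]
  for (int i = 0; i < 3; i++) {
    double Ri = R[i];
    for (int j = 0; j < 3; j++) {
      double Rj = R[j];
      double dij = (i == j) ? 1.0 : 0.0;
      double s = dij * iR + Ri * Rj * iR3;
      double term = h * (dij * iR3 - 3.0 * Ri * Rj * iR5)
        - (dij * R0 + ((j == 0) ? Ri : 0.0)) * iR3
        + ((i == 0) ? Rj * iR3 : 0.0)
        + 3.0 * Ri * R0 * Rj * iR5;
      double Mj = (j == 0) ? -1.0 : 1.0;
      acc[3 * i + j] += w * (-s + th * Mj * term);
    }
  }
}

static inline double dist2_point_tri(const double* x, const double* a,
                                     const double* b, const double* c) {
  // squared distance to the centroid: adequate for refinement decisions
  double d0 = x[0] - (a[0] + b[0] + c[0]) / 3.0;
  double d1 = x[1] - (a[1] + b[1] + c[1]) / 3.0;
  double d2 = x[2] - (a[2] + b[2] + c[2]) / 3.0;
  return d0 * d0 + d1 * d1 + d2 * d2;
}

static inline double tri_area2x(const double* a, const double* b,
                                const double* c, double* cr) {
  double e10 = b[0] - a[0], e11 = b[1] - a[1], e12 = b[2] - a[2];
  double e20 = c[0] - a[0], e21 = c[1] - a[1], e22 = c[2] - a[2];
  cr[0] = e11 * e22 - e12 * e21;
  cr[1] = e12 * e20 - e10 * e22;
  cr[2] = e10 * e21 - e11 * e20;
  return std::sqrt(cr[0] * cr[0] + cr[1] * cr[1] + cr[2] * cr[2]);
}

static inline double tri_diam2(const double* a, const double* b,
                               const double* c) {
  double m = 0.0;
  for (int pass = 0; pass < 3; pass++) {
    const double* p = pass == 0 ? a : (pass == 1 ? b : c);
    const double* q = pass == 0 ? b : (pass == 1 ? c : a);
    double d0 = p[0] - q[0], d1 = p[1] - q[1], d2 = p[2] - q[2];
    double d = d0 * d0 + d1 * d1 + d2 * d2;
    if (d > m) m = d;
  }
  return m;
}

static void quad7_pair(const double* x, const double* a, const double* b,
                       const double* c, double area, bool wall,
                       double* acc) {
  double y[3];
  for (int k = 0; k < 7; k++) {
    double la = 1.0 - QA[k] - QB[k];
    y[0] = la * a[0] + QA[k] * b[0] + QB[k] * c[0];
    y[1] = la * a[1] + QA[k] * b[1] + QB[k] * c[1];
    y[2] = la * a[2] + QA[k] * b[2] + QB[k] * c[2];
    double w = QW[k] * area;
    acc_stokeslet(x, y, w, acc);
    if (wall) acc_blake_image(x, y, w, acc);
  }
}

// adaptive integration over triangle (a,b,c) for collocation point x
// (ximg: its mirror through the wall; only used when wall is true)
static void quad_adaptive(const double* x, const double* ximg,
                          const double* a, const double* b, const double* c,
                          bool wall, int depth, double* acc) {
  double d2 = dist2_point_tri(x, a, b, c);
  if (wall) {
    double di = dist2_point_tri(ximg, a, b, c);
    if (di < d2) d2 = di;
  }
  double dm2 = tri_diam2(a, b, c);
  if (depth < 3 && d2 < 2.25 * dm2) {   // dist < 1.5 * diameter
    double ab[3], bc[3], ca[3];
    for (int d = 0; d < 3; d++) {
      ab[d] = 0.5 * (a[d] + b[d]);
      bc[d] = 0.5 * (b[d] + c[d]);
      ca[d] = 0.5 * (c[d] + a[d]);
    }
    quad_adaptive(x, ximg, a, ab, ca, wall, depth + 1, acc);
    quad_adaptive(x, ximg, ab, b, bc, wall, depth + 1, acc);
    quad_adaptive(x, ximg, ca, bc, c, wall, depth + 1, acc);
    quad_adaptive(x, ximg, ab, bc, ca, wall, depth + 1, acc);
  } else {
    double cr[3];
    double area = 0.5 * tri_area2x(a, b, c, cr);
    quad7_pair(x, a, b, c, area, wall, acc);
  }
}

// self element: Duffy polar split at the centroid (free-space part); the
// image part is regular there and handled by the adaptive rule
static void quad_self(const Tri& t, bool wall, double* acc) {
  const double* x = t.cen;
  const double* vv[4] = {t.v0, t.v1, t.v2, t.v0};
  double y[3], A[3], B[3], cr[3];
  for (int s = 0; s < 3; s++) {
    for (int d = 0; d < 3; d++) {
      A[d] = vv[s][d] - x[d];
      B[d] = vv[s + 1][d] - x[d];
    }
    double zero[3] = {0.0, 0.0, 0.0};
    double twoArea = tri_area2x(zero, A, B, cr);
    for (int iu = 0; iu < 8; iu++) {
      double u = GL8X[iu];
      for (int iv = 0; iv < 8; iv++) {
        double v = GL8X[iv];
        for (int d = 0; d < 3; d++)
          y[d] = x[d] + u * ((1.0 - v) * A[d] + v * B[d]);
        acc_stokeslet(x, y, GL8W[iu] * GL8W[iv] * u * twoArea, acc);
      }
    }
  }
  if (wall) {
    double ximg[3] = {-x[0], x[1], x[2]};
    double img[9] = {0};
    // adaptive integration of the image correction only
    struct Rec {
      static void go(const double* ximg, const double* x, const double* a,
                     const double* b, const double* c, int depth,
                     double* img) {
        double d2 = dist2_point_tri(ximg, a, b, c);
        double dm2 = tri_diam2(a, b, c);
        if (depth < 3 && d2 < 2.25 * dm2) {
          double ab[3], bc[3], ca[3];
          for (int d = 0; d < 3; d++) {
            ab[d] = 0.5 * (a[d] + b[d]);
            bc[d] = 0.5 * (b[d] + c[d]);
            ca[d] = 0.5 * (c[d] + a[d]);
          }
          go(ximg, x, a, ab, ca, depth + 1, img);
          go(ximg, x, ab, b, bc, depth + 1, img);
          go(ximg, x, ca, bc, c, depth + 1, img);
          go(ximg, x, ab, bc, ca, depth + 1, img);
        } else {
          double cr[3], y[3];
          double area = 0.5 * tri_area2x(a, b, c, cr);
          for (int k = 0; k < 7; k++) {
            double la = 1.0 - QA[k] - QB[k];
            for (int d = 0; d < 3; d++)
              y[d] = la * a[d] + QA[k] * b[d] + QB[k] * c[d];
            acc_blake_image(x, y, QW[k] * area, img);
          }
        }
      }
    };
    Rec::go(ximg, x, t.v0, t.v1, t.v2, 0, img);
    for (int k = 0; k < 9; k++) acc[k] += img[k];
  }
}

static std::vector<Tri> make_tris(const mat& nodes, const umat& tris) {
  int nt = tris.n_rows;
  std::vector<Tri> out(nt);
  for (int m = 0; m < nt; m++) {
    Tri& t = out[m];
    for (int d = 0; d < 3; d++) {
      t.v0[d] = nodes(tris(m, 0), d);
      t.v1[d] = nodes(tris(m, 1), d);
      t.v2[d] = nodes(tris(m, 2), d);
      t.cen[d] = (t.v0[d] + t.v1[d] + t.v2[d]) / 3.0;
    }
    double cr[3];
    double a2 = tri_area2x(t.v0, t.v1, t.v2, cr);
    t.area = 0.5 * a2;
    for (int d = 0; d < 3; d++) t.nrm[d] = cr[d] / a2;
    t.diam = std::sqrt(tri_diam2(t.v0, t.v1, t.v2));
  }
  return out;
}

// dense single-layer kernel matrix K (3N x 3N), blocks
// K_{mn} = (1/8pi) \int_{T_n} G(x_m, y) dS(y), plus rank-one deflation of
// the normal-density (interior pressure) null vector
static mat assemble_K(const std::vector<Tri>& T, bool wall) {
  int nt = T.size();
  mat K(3 * nt, 3 * nt);
  const double c = 1.0 / (8.0 * datum::pi);
  double acc[9];
  for (int m = 0; m < nt; m++) {
    const double* x = T[m].cen;
    double ximg[3] = {-x[0], x[1], x[2]};
    for (int n = 0; n < nt; n++) {
      for (int k = 0; k < 9; k++) acc[k] = 0.0;
      if (n == m)
        quad_self(T[n], wall, acc);
      else
        quad_adaptive(x, ximg, T[n].v0, T[n].v1, T[n].v2, wall, 0, acc);
      for (int i = 0; i < 3; i++)
        for (int j = 0; j < 3; j++)
          K(3 * m + i, 3 * n + j) = c * acc[3 * i + j];
    }
  }
  double s = 0.0;
  for (int i = 0; i < 3 * nt; i++) s += std::abs(K(i, i));
  s /= (3 * nt);
  double atot = 0.0;
  for (int n = 0; n < nt; n++) atot += T[n].area;
  for (int m = 0; m < nt; m++)
    for (int n = 0; n < nt; n++) {
      double w = s * T[n].area / atot;
      for (int i = 0; i < 3; i++)
        for (int j = 0; j < 3; j++)
          K(3 * m + i, 3 * n + j) += w * T[m].nrm[i] * T[n].nrm[j];
    }
  return K;
}

static mat skew(const double* r) {
  mat S(3, 3, fill::zeros);
  S(0, 1) = -r[2]; S(0, 2) = r[1];
  S(1, 0) = r[2];  S(1, 2) = -r[0];
  S(2, 0) = -r[1]; S(2, 1) = r[0];
  return S;
}

// shared assembly of the (3N+6) mobility system matrix
static mat mobility_matrix(const std::vector<Tri>& T, const vec& x0,
                           bool wall) {
  int nt = T.size();
  int N = 3 * nt + 6;
  mat A(N, N, fill::zeros);
  A.submat(0, 0, 3 * nt - 1, 3 * nt - 1) = assemble_K(T, wall);
  for (int m = 0; m < nt; m++) {
    double r[3] = {T[m].cen[0] - x0(0), T[m].cen[1] - x0(1),
                   T[m].cen[2] - x0(2)};
    A.submat(3 * m, 3 * nt, 3 * m + 2, 3 * nt + 2) = -eye(3, 3);
    A.submat(3 * m, 3 * nt + 3, 3 * m + 2, 3 * nt + 5) = skew(r);
    A.submat(3 * nt, 3 * m, 3 * nt + 2, 3 * m + 2) = T[m].area * eye(3, 3);
    A.submat(3 * nt + 3, 3 * m, 3 * nt + 5, 3 * m + 2) =
        T[m].area * skew(r);
  }
  return A;
}

// Mobility solve: unknowns [q (3N); U (3); Omega (3)].
// Collocation rows:  K q - U - Omega x r_m = uslip_m - ub_m
// Constraint rows:   sum A_n q_n = fext,  sum A_n r_n x q_n = text
// (fext, text are external force/torque divided by viscosity).
// [[Rcpp::export]]
Rcpp::List bem_mobility_cpp(const arma::mat& nodes, const arma::umat& tris,
                            const arma::mat& uslip, const arma::mat& ub,
                            const arma::vec& x0, const arma::vec& fext,
                            const arma::vec& text, bool wall) {
  std::vector<Tri> T = make_tris(nodes, tris);
  int nt = T.size();
  mat A = mobility_matrix(T, x0, wall);
  vec rhs(3 * nt + 6, fill::zeros);
  for (int m = 0; m < nt; m++)
    for (int i = 0; i < 3; i++)
      rhs(3 * m + i) = uslip(m, i) - ub(m, i);
  rhs.subvec(3 * nt, 3 * nt + 2) = fext;
  rhs.subvec(3 * nt + 3, 3 * nt + 5) = text;

  vec sol = solve(A, rhs, solve_opts::fast);
  vec resid = A * sol - rhs;

  mat q(nt, 3);
  for (int n = 0; n < nt; n++)
    for (int i = 0; i < 3; i++) q(n, i) = sol(3 * n + i);
  return Rcpp::List::create(
      Rcpp::Named("U") = sol.subvec(3 * nt, 3 * nt + 2),
      Rcpp::Named("Omega") = sol.subvec(3 * nt + 3, 3 * nt + 5),
      Rcpp::Named("q") = q,
      Rcpp::Named("residual") = norm(resid) / std::max(norm(rhs), 1e-300));
}

// Multi-right-hand-side mobility solve: the operator depends only on the
// geometry, so phase-field sweeps (many background flows at one frozen
// configuration and beat phase) reuse a single assembly and factorisation.
// ub is (nt x 3 x nrhs); fext, text are 3 x nrhs.
// [[Rcpp::export]]
Rcpp::List bem_mobility_multi_cpp(const arma::mat& nodes,
                                  const arma::umat& tris,
                                  const arma::mat& uslip,
                                  const arma::cube& ub, const arma::vec& x0,
                                  const arma::mat& fext, const arma::mat& text,
                                  bool wall) {
  std::vector<Tri> T = make_tris(nodes, tris);
  int nt = T.size();
  int nr = ub.n_slices;
  mat A = mobility_matrix(T, x0, wall);
  mat rhs(3 * nt + 6, nr, fill::zeros);
  for (int k = 0; k < nr; k++) {
    for (int m = 0; m < nt; m++)
      for (int i = 0; i < 3; i++)
        rhs(3 * m + i, k) = uslip(m, i) - ub(m, i, k);
    rhs.submat(3 * nt, k, 3 * nt + 2, k) = fext.col(k);
    rhs.submat(3 * nt + 3, k, 3 * nt + 5, k) = text.col(k);
  }
  mat sol = solve(A, rhs, solve_opts::fast);
  return Rcpp::List::create(
      Rcpp::Named("U") = mat(sol.rows(3 * nt, 3 * nt + 2)),
      Rcpp::Named("Omega") = mat(sol.rows(3 * nt + 3, 3 * nt + 5)));
}

// Resistance solve: surface velocity fully prescribed (u_el, lab frame);
// returns the hydrodynamic force and torque exerted on the body (divided by
// viscosity), i.e. -sum A_n q_n and -sum A_n r_n x q_n.
// [[Rcpp::export]]
Rcpp::List bem_resistance_cpp(const arma::mat& nodes, const arma::umat& tris,
                              const arma::mat& u_el, const arma::mat& ub,
                              const arma::vec& x0, bool wall) {
  std::vector<Tri> T = make_tris(nodes, tris);
  int nt = T.size();
  mat K = assemble_K(T, wall);
  vec rhs(3 * nt);
  for (int m = 0; m < nt; m++)
    for (int i = 0; i < 3; i++) rhs(3 * m + i) = u_el(m, i) - ub(m, i);
  vec q = solve(K, rhs, solve_opts::fast);
  vec F(3, fill::zeros), Tq(3, fill::zeros);
  mat qm(nt, 3);
  for (int n = 0; n < nt; n++) {
    double r[3] = {T[n].cen[0] - x0(0), T[n].cen[1] - x0(1),
                   T[n].cen[2] - x0(2)};
    for (int i = 0; i < 3; i++) {
      F(i) -= T[n].area * q(3 * n + i);
      qm(n, i) = q(3 * n + i);
    }
    Tq(0) -= T[n].area * (r[1] * q(3 * n + 2) - r[2] * q(3 * n + 1));
    Tq(1) -= T[n].area * (r[2] * q(3 * n + 0) - r[0] * q(3 * n + 2));
    Tq(2) -= T[n].area * (r[0] * q(3 * n + 1) - r[1] * q(3 * n + 0));
  }
  return Rcpp::List::create(Rcpp::Named("force") = F,
                            Rcpp::Named("torque") = Tq,
                            Rcpp::Named("q") = qm);
}
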