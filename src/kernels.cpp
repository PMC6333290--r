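// Green's functions of three-dimensional Stokes flow.
//
// Conventions: the velocity at x induced by a point force F at y is
// u_i(x) = G_ij(x, y) F_j / (8 pi mu).  The free-space (Oseen) tensor is
// G_ij = delta_ij/r + r_i r_j / r^3 with r = x - y.  The wall variant is the
// Blake image system enforcing no slip on the plane x1 = 0 (fluid in x1 > 0):
// a mirror stokeslet, a potential (source) dipole and a stokeslet doublet
// located at the image point.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

void stokeslet_G(const double* x, const double* y, mat& G) {
  double r0 = x[0] - y[0], r1 = x[1] - y[1], r2 = x[2] - y[2];
  double rr = std::sqrt(r0 * r0 + r1 * r1 + r2 * r2);
  double ir = 1.0 / rr, ir3 = ir * ir * ir;
  G(0, 0) = ir + r0 * r0 * ir3;
  G(1, 1) = ir + r1 * r1 * ir3;
  G(2, 2) = ir + r2 * r2 * ir3;
  G(0, 1) = G(1, 0) = r0 * r1 * ir3;
  G(0, 2) = G(2, 0) = r0 * r2 * ir3;
  G(1, 2) = G(2, 1) = r1 * r2 * ir3;
}

// Image-system correction: blake_G = stokeslet(r) + blake_image(x, y).
// Wall-normal coordinate is index 0 (plane x1 = 0).
void blake_image(const double* x, const double* y, mat& W) {
  double h = y[0];                              // source height above wall
  double R0 = x[0] + h, R1 = x[1] - y[1], R2 = x[2] - y[2];  // x - y_image
  double R[3] = {R0, R1, R2};
  double RR = std::sqrt(R0 * R0 + R1 * R1 + R2 * R2);
  double iR = 1.0 / RR, iR3 = iR * iR * iR, iR5 = iR3 * iR * iR;
  W.zeros();
  // minus the image stokeslet
  for (int i = 0; i < 3; i++) {
    for (int j = 0; j < 3; j++) {
      double s = (i == j ? iR : 0.0) + R[i] * R[j] * iR3;
      W(i, j) -= s;
    }
  }
  // 2 h M_j d/dR_j [ h R_i/R^3 - delta_{i0}/R - R_i R_0 / R^3 ],
  // M_j = -1 for the wall-normal direction (j = 0), +1 tangentially.
  for (int i = 0; i < 3; i++) {
    for (int j = 0; j < 3; j++) {
      double Mj = (j == 0) ? -1.0 : 1.0;
      double dij = (i == j) ? 1.0 : 0.0;
      double term = h * (dij * iR3 - 3.0 * R[i] * R[j] * iR5);
      term += (i == 0 ? R[j] * iR3 : 0.0);
      term -= (dij * R0 + (j == 0 ? R[i] : 0.0)) * iR3;
      term += 3.0 * R[i] * R0 * R[j] * iR5;
      W(i, j) += 2.0 * h * Mj * term;
    }
  }
}

// [[Rcpp::export]]
arma::mat stokeslet_cpp(const arma::vec& x, const arma::vec& y) {
  mat G(3, 3);
  stokeslet_G(x.memptr(), y.memptr(), G);
  return G;
}

// Stress Green's function (free space): T_ijk = -6 r_i r_j r_k / r^5,
// returned as a 3x3x3 cube with u ~ u_i T_ijk n_k structure.
// [[Rcpp::export]]
arma::cube stresslet_cpp(const arma::vec& x, const arma::vec& y) {
  vec r = x - y;
  double rr = norm(r), ir5 = 1.0 / std::pow(rr, 5);
  cube T(3, 3, 3);
  for (int i = 0; i < 3; i++)
    for (int j = 0; j < 3; j++)
      for (int k = 0; k < 3; k++)
        T(i, j, k) = -6.0 * r(i) * r(j) * r(k) * ir5;
  return T;
}

// [[Rcpp::export]]
arma::mat blake_cpp(const arma::vec& x, const arma::vec& y) {
  mat G(3, 3), W(3, 3);
  stokeslet_G(x.memptr(), y.memptr(), G);
  blake_image(x.memptr(), y.memptr(), W);
  return G + W;
}
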