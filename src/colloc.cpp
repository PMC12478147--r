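// Implicit-midpoint collocation residual and Jacobian triplets for the
// half-ring elastica system (states kappa, kappa', theta, x, y, area).
#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
NumericVector colloc_residual_cpp(NumericVector z, int n, double h,
                                  double d, double A) {
  const int m = n - 1;
  NumericVector out(6 * m + 8);
  const double lambda0 = z[6 * n], p = z[6 * n + 1];
  for (int i = 0; i < m; ++i) {
    const double *yi = &z[6 * i], *yj = &z[6 * (i + 1)];
    double k = 0.5 * (yi[0] + yj[0]);
    double k2 = 0.5 * (yi[1] + yj[1]);
    double th = 0.5 * (yi[2] + yj[2]);
    double x = 0.5 * (yi[3] + yj[3]);
    double y = 0.5 * (yi[4] + yj[4]);
    double c = std::cos(th), s = std::sin(th);
    double f[6] = {k2, -0.5 * k * k * k + lambda0 * k - p, k, c, s,
                   y * c - x * s};
    for (int q = 0; q < 6; ++q)
      out[6 * i + q] = yj[q] - yi[q] - h * f[q];
  }
  const double *y1 = &z[0], *yn = &z[6 * (n - 1)];
  out[6 * m + 0] = y1[2] - M_PI / 2;
  out[6 * m + 1] = y1[3];
  out[6 * m + 2] = y1[4];
  out[6 * m + 3] = y1[5];
  out[6 * m + 4] = yn[2] + M_PI / 2;
  out[6 * m + 5] = yn[3] - d;
  out[6 * m + 6] = yn[4];
  out[6 * m + 7] = yn[5] - A;
  return out;
}

// [[Rcpp::export]]
List colloc_jacobian_cpp(NumericVector z, int n, double h) {
  const int m = n - 1;
  // per interval: 8 rhs-Jacobian entries x 2 blocks + 12 identity + 2 params
  const int nz = m * (8 * 2 + 12 + 2) + 8;
  IntegerVector ii(nz), jj(nz);
  NumericVector vv(nz);
  const double lambda0 = z[6 * n];
  int t = 0;
  for (int i = 0; i < m; ++i) {
    const double *yi = &z[6 * i], *yj = &z[6 * (i + 1)];
    double k = 0.5 * (yi[0] + yj[0]);
    double th = 0.5 * (yi[2] + yj[2]);
    double x = 0.5 * (yi[3] + yj[3]);
    double y = 0.5 * (yi[4] + yj[4]);
    double c = std::cos(th), s = std::sin(th);
    // nonzeros of J_f: (row, col, value)
    int jr[8] = {0, 1, 2, 3, 4, 5, 5, 5};
    int jc[8] = {1, 0, 0, 2, 2, 2, 3, 4};
    double jv[8] = {1.0, -1.5 * k * k + lambda0, 1.0, -s, c,
                    -y * s - x * c, -s, c};
    const int r0 = 6 * i, cA = 6 * i, cB = 6 * (i + 1);
    for (int q = 0; q < 8; ++q) {
      double v = -0.5 * h * jv[q];
      ii[t] = r0 + jr[q] + 1; jj[t] = cA + jc[q] + 1; vv[t] = v; ++t;
      ii[t] = r0 + jr[q] + 1; jj[t] = cB + jc[q] + 1; vv[t] = v; ++t;
    }
    for (int q = 0; q < 6; ++q) {
      ii[t] = r0 + q + 1; jj[t] = cA + q + 1; vv[t] = -1.0; ++t;
      ii[t] = r0 + q + 1; jj[t] = cB + q + 1; vv[t] = 1.0; ++t;
    }
    ii[t] = r0 + 2; jj[t] = 6 * n + 1; vv[t] = -h * k; ++t;   // d/dlambda0
    ii[t] = r0 + 2; jj[t] = 6 * n + 2; vv[t] = h; ++t;        // d/dp
  }
  const int nb = 6 * m;
  int bc_j[8] = {3, 4, 5, 6, 6 * (n - 1) + 3, 6 * (n - 1) + 4,
                 6 * (n - 1) + 5, 6 * (n - 1) + 6};
  for (int q = 0; q < 8; ++q) {
    ii[t] = nb + q + 1; jj[t] = bc_j[q]; vv[t] = 1.0; ++t;
  }
  return List::create(_["i"] = ii, _["j"] = jj, _["x"] = vv);
}
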