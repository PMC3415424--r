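#include <Rcpp.h>
using namespace Rcpp;

// Bilinear sample of m at (x + dx, y + dy); zero outside the image.
// Column-major pointer walk with a branch-free interior so the hot loop
// vectorizes; every endstopped channel samples its flanker maps at
// continuous displacements, so this is the pipeline's hot spot.
// [[Rcpp::export]]
NumericMatrix shift_bilinear(const NumericMatrix& m, double dx, double dy) {
  const int ny = m.nrow(), nx = m.ncol();
  const int fx = (int)std::floor(dx), fy = (int)std::floor(dy);
  const double ax = dx - fx, ay = dy - fy;
  const double w00 = (1 - ax) * (1 - ay), w10 = ax * (1 - ay),
               w01 = (1 - ax) * ay, w11 = ax * ay;
  NumericMatrix out(ny, nx);
  const double* M = &m[0];
  double* O = &out[0];
  // rows whose two source rows are both in range
  const int y0 = std::max(0, -fy);
  const int y1 = std::min(ny, ny - 1 - fy);
  for (int x = 0; x < nx; ++x) {
    double* o = O + (size_t)x * ny;
    const int sx0 = x + fx, sx1 = sx0 + 1;
    const bool ok0 = sx0 >= 0 && sx0 < nx, ok1 = sx1 >= 0 && sx1 < nx;
    if (!ok0 && !ok1) continue;
    const double* c0 = ok0 ? M + (size_t)sx0 * ny : 0;
    const double* c1 = ok1 ? M + (size_t)sx1 * ny : 0;
    if (ok0 && ok1) {
      for (int y = y0; y < y1; ++y) {
        o[y] = w00 * c0[y + fy] + w10 * c1[y + fy] +
               w01 * c0[y + fy + 1] + w11 * c1[y + fy + 1];
      }
    } else if (ok0) {
      for (int y = y0; y < y1; ++y) {
        o[y] = w00 * c0[y + fy] + w01 * c0[y + fy + 1];
      }
    } else {
      for (int y = y0; y < y1; ++y) {
        o[y] = w10 * c1[y + fy] + w11 * c1[y + fy + 1];
      }
    }
    for (int y = 0; y < ny; ++y) {
      if (y >= y0 && y < y1) continue;
      const int sy0 = y + fy, sy1 = sy0 + 1;
      double v = 0.0;
      if (sy0 >= 0 && sy0 < ny) {
        if (ok0) v += w00 * c0[sy0];
        if (ok1) v += w10 * c1[sy0];
      }
      if (sy1 >= 0 && sy1 < ny) {
        if (ok0) v += w01 * c0[sy1];
        if (ok1) v += w11 * c1[sy1];
      }
      o[y] = v;
    }
  }
  return out;
}

// Rectified difference of a center map and two weighted displaced
// flanker maps: relu(cc * s - cf * f1 - cf * f2), fused in one pass.
// [[Rcpp::export]]
NumericMatrix endstop_combine(const NumericMatrix& s,
                              const NumericMatrix& f1,
                              const NumericMatrix& f2,
                              double cc, double cf) {
  const R_xlen_t n = s.size();
  NumericMatrix out(s.nrow(), s.ncol());
  const double* S = &s[0];
  const double* F1 = &f1[0];
  const double* F2 = &f2[0];
  double* O = &out[0];
  for (R_xlen_t i = 0; i < n; ++i) {
    const double v = cc * S[i] - cf * F1[i] - cf * F2[i];
    O[i] = v > 0 ? v : 0;
  }
  return out;
}

// Weighted sum of bilinear-shifted copies of one map (the complex-cell
// pooling stage): sum_k w[k] * shift(m, k-th displacement).
// [[Rcpp::export]]
NumericMatrix pool_shifted(const NumericMatrix& m,
                           const NumericVector& dxs,
                           const NumericVector& dys,
                           const NumericVector& w) {
  const int ny = m.nrow(), nx = m.ncol();
  NumericMatrix acc(ny, nx);
  double* A = &acc[0];
  for (int k = 0; k < w.size(); ++k) {
    NumericMatrix s = shift_bilinear(m, dxs[k], dys[k]);
    const double* S = &s[0];
    const double wk = w[k];
    const R_xlen_t n = (R_xlen_t)ny * nx;
    for (R_xlen_t i = 0; i < n; ++i) A[i] += wk * S[i];
  }
  return acc;
}
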