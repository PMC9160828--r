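#include <Rcpp.h>
using namespace Rcpp;

// Cascade of second-order sections applied along the columns of x
// (direct form II transposed). sos rows: b0 b1 b2 1 a1 a2.
// [[Rcpp::export]]
NumericMatrix sosfilt_cpp(NumericMatrix sos, NumericMatrix x) {
  int ns = sos.nrow();
  int n = x.nrow(), nch = x.ncol();
  NumericMatrix y = clone(x);
  for (int c = 0; c < nch; ++c) {
    for (int s = 0; s < ns; ++s) {
      double b0 = sos(s, 0), b1 = sos(s, 1), b2 = sos(s, 2);
      double a1 = sos(s, 4), a2 = sos(s, 5);
      double z1 = 0.0, z2 = 0.0;
      for (int t = 0; t < n; ++t) {
        double xt = y(t, c);
        double yt = b0 * xt + z1;
        z1 = b1 * xt - a1 * yt + z2;
        z2 = b2 * xt - a2 * yt;
        y(t, c) = yt;
      }
    }
  }
  return y;
}

// Zero-phase (forward-backward) SOS filtering with odd-reflection padding,
// all in one pass per direction with the section cascade fused per sample.
// [[Rcpp::export]]
NumericMatrix sosfiltfilt_cpp(NumericMatrix sos, NumericMatrix x, int pad) {
  int ns = sos.nrow();
  int n = x.nrow(), nch = x.ncol();
  if (pad > n - 1) pad = n - 1;
  if (pad < 0) pad = 0;
  int m = n + 2 * pad;
  NumericMatrix out(n, nch);
  std::vector<double> buf(m), z1(ns), z2(ns);
  for (int c = 0; c < nch; ++c) {
    // odd reflection at both ends
    for (int t = 0; t < pad; ++t) buf[t] = 2.0 * x(0, c) - x(pad - t, c);
    for (int t = 0; t < n; ++t) buf[pad + t] = x(t, c);
    for (int t = 0; t < pad; ++t)
      buf[pad + n + t] = 2.0 * x(n - 1, c) - x(n - 2 - t, c);
    for (int dir = 0; dir < 2; ++dir) {
      std::fill(z1.begin(), z1.end(), 0.0);
      std::fill(z2.begin(), z2.end(), 0.0);
      for (int t = 0; t < m; ++t) {
        int idx = dir == 0 ? t : m - 1 - t;
        double v = buf[idx];
        for (int s = 0; s < ns; ++s) {
          double b0 = sos(s, 0), b1 = sos(s, 1), b2 = sos(s, 2);
          double a1 = sos(s, 4), a2 = sos(s, 5);
          double yt = b0 * v + z1[s];
          z1[s] = b1 * v - a1 * yt + z2[s];
          z2[s] = b2 * v - a2 * yt;
          v = yt;
        }
        buf[idx] = v;
      }
    }
    for (int t = 0; t < n; ++t) out(t, c) = buf[pad + t];
  }
  return out;
}
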