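#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Median-conserving decimation: per-window medians over a repeating window
// length pattern (e.g. c(6, 6, 6, 7) for 500 kHz -> 80 kHz). Trailing
// samples that do not fill a window are dropped.
// [[Rcpp::export]]
NumericVector decimate_median_cpp(NumericVector x, IntegerVector pattern) {
  const R_xlen_t n = x.size();
  const int np = pattern.size();
  // count complete windows
  R_xlen_t pos = 0, nout = 0;
  int pi = 0;
  while (pos + pattern[pi] <= n) {
    pos += pattern[pi];
    pi = (pi + 1) % np;
    ++nout;
  }
  NumericVector out(nout);
  std::vector<double> buf;
  pos = 0; pi = 0;
  for (R_xlen_t w = 0; w < nout; ++w) {
    const int len = pattern[pi];
    buf.assign(x.begin() + pos, x.begin() + pos + len);
    const int mid = len / 2;
    std::nth_element(buf.begin(), buf.begin() + mid, buf.end());
    double med = buf[mid];
    if (len % 2 == 0) {
      double lo = *std::max_element(buf.begin(), buf.begin() + mid);
      med = (med + lo) / 2.0;
    }
    out[w] = med;
    pos += len;
    pi = (pi + 1) % np;
  }
  return out;
}

// im2col gather for 1D convolution. x is the flattened (n, L, C) activation
// array (sample index fastest); off holds the K*C column offsets. Returns
// the (n*Lo) x (K*C) patch matrix whose product with the (K*C) x F weight
// matrix is the convolution output.
// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector x, int n_rows, IntegerVector off) {
  const int nc = off.size();
  NumericMatrix out(n_rows, nc);
  for (int j = 0; j < nc; ++j) {
    const R_xlen_t o = off[j];
    const double *src = x.begin() + o;
    double *dst = &out(0, j);
    std::copy(src, src + n_rows, dst);
  }
  return out;
}

// col2im scatter-add: accumulates patch-matrix gradients back onto the
// flattened input array (inverse of im2col_cpp).
// [[Rcpp::export]]
NumericVector col2im_cpp(NumericMatrix dcol, R_xlen_t x_len, IntegerVector off) {
  const int nc = off.size();
  const int n_rows = dcol.nrow();
  NumericVector dx(x_len);
  for (int j = 0; j < nc; ++j) {
    const R_xlen_t o = off[j];
    const double *src = &dcol(0, j);
    double *dst = dx.begin() + o;
    for (int r = 0; r < n_rows; ++r) dst[r] += src[r];
  }
  return dx;
}
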