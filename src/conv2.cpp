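#include <Rcpp.h>
using namespace Rcpp;

// Zero-padded, same-size 2D cross-correlation:
//   out(i, j) = sum_{u, v} K(u, v) * X(i + u - hr, j + v - hc)
// with K of odd size (2*hr+1) x (2*hc+1).  For the centro-symmetric DoG
// kernels used throughout the package this equals convolution.
// Implemented as one shifted multiply-add pass over the image per kernel
// element so the inner loops run over contiguous memory.
// [[Rcpp::export]]
NumericMatrix conv2_same(const NumericMatrix& X, const NumericMatrix& K) {
  const int nr = X.nrow(), nc = X.ncol();
  const int kr = K.nrow(), kc = K.ncol();
  if (kr % 2 == 0 || kc % 2 == 0)
    stop("kernel must have odd dimensions");
  const int hr = (kr - 1) / 2, hc = (kc - 1) / 2;
  NumericMatrix out(nr, nc);
  const double* x = X.begin();
  double* o = out.begin();
  for (int v = 0; v < kc; ++v) {
    const int dj = v - hc;                    // column shift
    const int jlo = std::max(0, -dj), jhi = std::min(nc, nc - dj);
    for (int u = 0; u < kr; ++u) {
      const double w = K(u, v);
      if (w == 0.0) continue;
      const int di = u - hr;                  // row shift
      const int ilo = std::max(0, -di), ihi = std::min(nr, nr - di);
      for (int j = jlo; j < jhi; ++j) {
        double* ocol = o + (size_t)j * nr;
        const double* xcol = x + (size_t)(j + dj) * nr + di;
        for (int i = ilo; i < ihi; ++i) ocol[i] += w * xcol[i];
      }
    }
  }
  return out;
}

// Gradient of sum(G * conv2_same(X, K)) with respect to the kernel K:
//   dK(u, v) = sum_{i, j} G(i, j) * X(i + u - hr, j + v - hc)
// returned as a (2*hr+1) x (2*hc+1) matrix; one shifted dot product per
// kernel element.
// [[Rcpp::export]]
NumericMatrix conv2_kernel_grad(const NumericMatrix& X, const NumericMatrix& G,
                                int hr, int hc) {
  const int nr = X.nrow(), nc = X.ncol();
  if (G.nrow() != nr || G.ncol() != nc)
    stop("X and G must have identical dimensions");
  NumericMatrix out(2 * hr + 1, 2 * hc + 1);
  const double* x = X.begin();
  const double* g = G.begin();
  for (int v = 0; v < 2 * hc + 1; ++v) {
    const int dj = v - hc;
    const int jlo = std::max(0, -dj), jhi = std::min(nc, nc - dj);
    for (int u = 0; u < 2 * hr + 1; ++u) {
      const int di = u - hr;
      const int ilo = std::max(0, -di), ihi = std::min(nr, nr - di);
      double s = 0.0;
      for (int j = jlo; j < jhi; ++j) {
        const double* gcol = g + (size_t)j * nr;
        const double* xcol = x + (size_t)(j + dj) * nr + di;
        for (int i = ilo; i < ihi; ++i) s += gcol[i] * xcol[i];
      }
      out(u, v) = s;
    }
  }
  return out;
}
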