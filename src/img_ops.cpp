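// Small image filters: separable Gaussian smoothing with symmetric boundary
// (for SSIM local statistics) and a sliding-window median.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static inline int refl(int i, int n) {  // symmetric half-sample reflection
  while (i < 0 || i >= n) {
    if (i < 0) i = -1 - i;
    if (i >= n) i = 2 * n - 1 - i;
  }
  return i;
}

// [[Rcpp::export]]
arma::mat cpp_sep_filter(const arma::mat& img, const arma::vec& kernel) {
  const int H = img.n_rows, W = img.n_cols, m = kernel.n_elem, h = m / 2;
  mat tmp(H, W), out(H, W);
  for (int c = 0; c < W; ++c) {       // along rows
    const double* src = img.colptr(c);
    double* dst = tmp.colptr(c);
    for (int r = 0; r < H; ++r) {
      double s = 0;
      for (int i = 0; i < m; ++i) s += kernel[i] * src[refl(r + i - h, H)];
      dst[r] = s;
    }
  }
  for (int r = 0; r < H; ++r) {       // along columns
    for (int c = 0; c < W; ++c) {
      double s = 0;
      for (int i = 0; i < m; ++i) s += kernel[i] * tmp(r, refl(c + i - h, W));
      out(r, c) = s;
    }
  }
  return out;
}

// [[Rcpp::export]]
arma::mat cpp_median_filter(const arma::mat& img, int k) {
  const int H = img.n_rows, W = img.n_cols, h = k / 2;
  mat out(H, W);
  std::vector<double> buf((size_t)k * k);
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      size_t m = 0;
      for (int dc = -h; dc <= h; ++dc)
        for (int dr = -h; dr <= h; ++dr)
          buf[m++] = img(refl(r + dr, H), refl(c + dc, W));
      std::nth_element(buf.begin(), buf.begin() + m / 2, buf.begin() + m);
      out(r, c) = buf[m / 2];
    }
  return out;
}
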