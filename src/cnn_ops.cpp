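// Convolution / transposed-convolution primitives for the encoder-decoder
// network, implemented as im2col/col2im plus BLAS gemm (via Armadillo).
//
// Batch layout: a batch is a (H*W*C) x N matrix, one sample per column.
// Within a column the C channel planes are stacked; each plane is
// column-major with H rows (R matrix convention), i.e.
//   index = c*H*W + col*H + row.
// All kernels are 3x3 with zero padding 1. Stride s gives an output edge of
// floor((H-1)/s)+1 (H for s=1, H/2 for even H at s=2). A transposed
// convolution with stride s maps H -> H*s and is the exact adjoint of the
// corresponding strided convolution.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static inline int out_edge(int H, int stride) { return (H - 1) / stride + 1; }

// col matrix: (9*Cin) x (Ho*Wo); row index = ci*9 + (dc+1)*3 + (dr+1)
static void im2col3(const double* x, int H, int W, int C, int stride,
                    mat& col) {
  const int Ho = out_edge(H, stride), Wo = out_edge(W, stride);
  col.zeros(9 * C, (size_t)Ho * Wo);
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const size_t pix = (size_t)wo * Ho + ho;
      double* dst = col.colptr(pix);
      for (int ci = 0; ci < C; ++ci) {
        const double* plane = x + (size_t)ci * H * W;
        for (int dc = -1; dc <= 1; ++dc) {
          const int wb = wo * stride + dc;
          if (wb < 0 || wb >= W) continue;
          const double* src = plane + (size_t)wb * H;
          for (int dr = -1; dr <= 1; ++dr) {
            const int hb = ho * stride + dr;
            if (hb < 0 || hb >= H) continue;
            dst[ci * 9 + (dc + 1) * 3 + (dr + 1)] = src[hb];
          }
        }
      }
    }
  }
}

// adjoint of im2col3: scatter-add col back onto the (H*W*C) image
static void col2im3(const mat& col, int H, int W, int C, int stride,
                    double* x) {
  const int Ho = out_edge(H, stride), Wo = out_edge(W, stride);
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const size_t pix = (size_t)wo * Ho + ho;
      const double* src = col.colptr(pix);
      for (int ci = 0; ci < C; ++ci) {
        double* plane = x + (size_t)ci * H * W;
        for (int dc = -1; dc <= 1; ++dc) {
          const int wb = wo * stride + dc;
          if (wb < 0 || wb >= W) continue;
          double* dst = plane + (size_t)wb * H;
          for (int dr = -1; dr <= 1; ++dr) {
            const int hb = ho * stride + dr;
            if (hb < 0 || hb >= H) continue;
            dst[hb] += src[ci * 9 + (dc + 1) * 3 + (dr + 1)];
          }
        }
      }
    }
  }
}

// W: (Cout x 9*Cin), b: Cout. Returns (Ho*Wo*Cout) x N.
// [[Rcpp::export]]
arma::mat cpp_conv_fwd(const arma::mat& X, const arma::mat& W,
                       const arma::vec& b, int H, int Wd, int Cin,
                       int stride) {
  const int Cout = W.n_rows, N = X.n_cols;
  const int Ho = out_edge(H, stride), Wo = out_edge(Wd, stride);
  const size_t P = (size_t)Ho * Wo;
  mat Y(P * Cout, N), col;
  for (int n = 0; n < N; ++n) {
    im2col3(X.colptr(n), H, Wd, Cin, stride, col);
    mat yc = W * col;            // Cout x P
    yc.each_col() += b;
    Y.col(n) = vectorise(yc.t());
  }
  return Y;
}

// [[Rcpp::export]]
Rcpp::List cpp_conv_bwd(const arma::mat& X, const arma::mat& W,
                        const arma::mat& GY, int H, int Wd, int Cin,
                        int stride) {
  const int Cout = W.n_rows, N = X.n_cols;
  const int Ho = out_edge(H, stride), Wo = out_edge(Wd, stride);
  const size_t P = (size_t)Ho * Wo;
  mat GX(X.n_rows, N, fill::zeros), GW(size(W), fill::zeros), col;
  vec Gb(Cout, fill::zeros);
  for (int n = 0; n < N; ++n) {
    im2col3(X.colptr(n), H, Wd, Cin, stride, col);
    mat gyc = reshape(GY.col(n), P, Cout).t();   // Cout x P
    GW += gyc * col.t();
    Gb += sum(gyc, 1);
    mat gcol = W.t() * gyc;                      // 9Cin x P
    col2im3(gcol, H, Wd, Cin, stride, GX.colptr(n));
  }
  return Rcpp::List::create(Rcpp::Named("gx") = GX, Rcpp::Named("gw") = GW,
                            Rcpp::Named("gb") = Gb);
}

// Transposed convolution. Wd: (9*Cout x Cin), b: Cout.
// Input edge Hs maps to Hs*stride. Returns (Hb*Wb*Cout) x N.
// [[Rcpp::export]]
arma::mat cpp_deconv_fwd(const arma::mat& X, const arma::mat& Wd,
                         const arma::vec& b, int Hs, int Ws, int Cin,
                         int stride) {
  const int Cout = Wd.n_rows / 9, N = X.n_cols;
  const int Hb = Hs * stride, Wb = Ws * stride;
  const size_t Ps = (size_t)Hs * Ws, Pb = (size_t)Hb * Wb;
  mat Y(Pb * Cout, N, fill::zeros);
  for (int n = 0; n < N; ++n) {
    mat xc = reshape(X.col(n), Ps, Cin).t();     // Cin x Ps
    mat colb = Wd * xc;                          // 9Cout x Ps
    col2im3(colb, Hb, Wb, Cout, stride, Y.colptr(n));
    double* y = Y.colptr(n);
    for (int co = 0; co < Cout; ++co) {
      double* plane = y + (size_t)co * Pb;
      for (size_t i = 0; i < Pb; ++i) plane[i] += b[co];
    }
  }
  return Y;
}

// [[Rcpp::export]]
Rcpp::List cpp_deconv_bwd(const arma::mat& X, const arma::mat& Wd,
                          const arma::mat& GY, int Hs, int Ws, int Cin,
                          int stride) {
  const int Cout = Wd.n_rows / 9, N = X.n_cols;
  const int Hb = Hs * stride, Wb = Ws * stride;
  const size_t Ps = (size_t)Hs * Ws, Pb = (size_t)Hb * Wb;
  mat GX(X.n_rows, N), GW(size(Wd), fill::zeros), colg;
  vec Gb(Cout, fill::zeros);
  for (int n = 0; n < N; ++n) {
    im2col3(GY.colptr(n), Hb, Wb, Cout, stride, colg);  // 9Cout x Ps
    mat xc = reshape(X.col(n), Ps, Cin).t();            // Cin x Ps
    GW += colg * xc.t();
    mat gxc = Wd.t() * colg;                            // Cin x Ps
    GX.col(n) = vectorise(gxc.t());
    const double* gy = GY.colptr(n);
    for (int co = 0; co < Cout; ++co) {
      const double* plane = gy + (size_t)co * Pb;
      double s = 0;
      for (size_t i = 0; i < Pb; ++i) s += plane[i];
      Gb[co] += s;
    }
  }
  return Rcpp::List::create(Rcpp::Named("gx") = GX, Rcpp::Named("gw") = GW,
                            Rcpp::Named("gb") = Gb);
}
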