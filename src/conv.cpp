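#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// 3x3 "same" (zero-padded) convolution over a (H, W, N, C) feature map by
// im2col + BLAS matmul. Wm is the (9*C x Cout) kernel matrix with channel
// fastest within each (kx, ky) block, matching the R-side array layout
// (Cin, 3, 3, Cout). Each im2col column is built as one shifted plane copy
// plus edge fixups. Returns y (H*W*N x Cout) and, when keep_col, the col
// matrix needed for the weight gradient.
// [[Rcpp::export]]
List conv2d3x3_cpp(NumericVector x, IntegerVector dims, arma::mat Wm,
                   arma::vec b, bool keep_col) {
  const int H = dims[0], W = dims[1], N = dims[2], C = dims[3];
  const arma::uword HW = (arma::uword)H * W;
  const arma::uword rows = HW * N;
  arma::mat col(rows, 9 * C);
  const double* xp = x.begin();
  for (int kx = 0; kx < 3; kx++)
    for (int ky = 0; ky < 3; ky++) {
      const int d = (ky - 1) + (kx - 1) * H;  // source offset within a plane
      for (int c = 0; c < C; c++) {
        double* dstc = col.colptr((kx * 3 + ky) * C + c);
        for (int n = 0; n < N; n++) {
          const double* src = xp + (arma::uword)c * HW * N + (arma::uword)n * HW;
          double* dst = dstc + (arma::uword)n * HW;
          if (d >= 0) {
            std::memcpy(dst, src + d, (HW - d) * sizeof(double));
            std::fill(dst + HW - d, dst + HW, 0.0);
          } else {
            std::fill(dst, dst - d, 0.0);
            std::memcpy(dst - d, src, (HW + d) * sizeof(double));
          }
          // zero the row wrapped across column boundaries
          if (ky == 0) for (int j = 0; j < W; j++) dst[(arma::uword)j * H] = 0.0;
          if (ky == 2) for (int j = 0; j < W; j++) dst[(arma::uword)j * H + H - 1] = 0.0;
          // zero columns whose source column is out of range
          if (kx == 0) std::fill(dst, dst + H, 0.0);
          if (kx == 2) std::fill(dst + (arma::uword)(W - 1) * H, dst + HW, 0.0);
        }
      }
    }
  arma::mat y = col * Wm;
  y.each_row() += b.t();
  List out = List::create(_["y"] = y);
  if (keep_col) out["col"] = col;
  return out;
}
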