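// Minimal CNN kernels: im2col convolution (forward/backward), nearest-neighbour
// upsampling, valid-mode 2-D correlation and bilinear affine warping.
// Images and feature maps are arma::cube with dimensions (H, W, C).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// Unfold x (H x W x Cin, zero-padded by `pad`) into an (Ho*Wo) x (kh*kw*Cin)
// matrix: one row per output position. The output-position index runs along
// columns of x, so both reads and writes are contiguous in memory.
static mat im2col(const cube& x, int kh, int kw, int stride, int pad,
                  int Ho, int Wo) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  mat cols((size_t)Ho * Wo, kh * kw * C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    const double* xs = x.slice_memptr(c);
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        double* dst = cols.colptr((size_t)c * kh * kw + kj * kh + ki);
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * stride - pad + kj;
          if (wi < 0 || wi >= W) continue;
          const double* col = xs + (size_t)wi * H;
          double* out = dst + (size_t)wo * Ho;
          const int hi0 = -pad + ki;
          for (int ho = 0; ho < Ho; ++ho) {
            const int hi = ho * stride + hi0;
            if (hi >= 0 && hi < H) out[ho] = col[hi];
          }
        }
      }
    }
  }
  return cols;
}

static void col2im_add(cube& gx, const mat& cols, int kh, int kw, int stride,
                       int pad, int Ho, int Wo) {
  const int H = gx.n_rows, W = gx.n_cols, C = gx.n_slices;
  for (int c = 0; c < C; ++c) {
    double* gs = gx.slice_memptr(c);
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const double* src = cols.colptr((size_t)c * kh * kw + kj * kh + ki);
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * stride - pad + kj;
          if (wi < 0 || wi >= W) continue;
          double* col = gs + (size_t)wi * H;
          const double* in = src + (size_t)wo * Ho;
          const int hi0 = -pad + ki;
          for (int ho = 0; ho < Ho; ++ho) {
            const int hi = ho * stride + hi0;
            if (hi >= 0 && hi < H) col[hi] += in[ho];
          }
        }
      }
    }
  }
}

// W is stored as a (kh*kw*Cin) x Cout matrix (column = one output filter).
// [[Rcpp::export]]
arma::cube conv_fwd(const arma::cube& x, const arma::mat& W,
                    const arma::vec& b, int kh, int kw, int stride, int pad) {
  const int Ho = (int)((x.n_rows + 2 * pad - kh) / stride) + 1;
  const int Wo = (int)((x.n_cols + 2 * pad - kw) / stride) + 1;
  const int Cout = W.n_cols;
  mat cols = im2col(x, kh, kw, stride, pad, Ho, Wo);
  cube y(Ho, Wo, Cout);
  mat out(y.memptr(), (size_t)Ho * Wo, Cout, false, true);
  out = cols * W;                    // (Ho*Wo) x Cout, aliasing y's memory
  out.each_row() += b.t();
  return y;
}

// The im2col matrix is recomputed from x (cheaper than shipping it back to
// R); with needInput = false the input gradient is skipped and an empty cube
// returned.
// [[Rcpp::export]]
Rcpp::List conv_bwd(const arma::cube& x, const arma::mat& W, int kh, int kw,
                    int stride, int pad, const arma::cube& gy,
                    bool needInput) {
  const int Ho = gy.n_rows, Wo = gy.n_cols, Cout = gy.n_slices;
  const mat gout(const_cast<cube&>(gy).memptr(), (size_t)Ho * Wo, Cout,
                 false, true);
  mat cols = im2col(x, kh, kw, stride, pad, Ho, Wo);
  mat gW = cols.t() * gout;          // (kh*kw*Cin) x Cout
  vec gb = sum(gout, 0).t();
  cube gx(needInput ? x.n_rows : 0, needInput ? x.n_cols : 0,
          needInput ? x.n_slices : 0, fill::zeros);
  if (needInput) {
    mat gcols = gout * W.t();        // (Ho*Wo) x (kh*kw*Cin)
    col2im_add(gx, gcols, kh, kw, stride, pad, Ho, Wo);
  }
  return Rcpp::List::create(Rcpp::Named("gx") = gx,
                            Rcpp::Named("gW") = gW,
                            Rcpp::Named("gb") = gb);
}

// [[Rcpp::export]]
arma::cube upsample2_fwd(const arma::cube& x) {
  cube y(2 * x.n_rows, 2 * x.n_cols, x.n_slices);
  for (uword c = 0; c < x.n_slices; ++c)
    for (uword j = 0; j < x.n_cols; ++j)
      for (uword i = 0; i < x.n_rows; ++i) {
        const double v = x(i, j, c);
        y(2 * i, 2 * j, c) = v;
        y(2 * i + 1, 2 * j, c) = v;
        y(2 * i, 2 * j + 1, c) = v;
        y(2 * i + 1, 2 * j + 1, c) = v;
      }
  return y;
}

// [[Rcpp::export]]
arma::cube upsample2_bwd(const arma::cube& gy) {
  cube gx(gy.n_rows / 2, gy.n_cols / 2, gy.n_slices);
  for (uword c = 0; c < gy.n_slices; ++c)
    for (uword j = 0; j < gx.n_cols; ++j)
      for (uword i = 0; i < gx.n_rows; ++i)
        gx(i, j, c) = gy(2 * i, 2 * j, c) + gy(2 * i + 1, 2 * j, c) +
                      gy(2 * i, 2 * j + 1, c) + gy(2 * i + 1, 2 * j + 1, c);
  return gx;
}

// Valid-mode 2-D cross-correlation of a single-channel image with a kernel;
// used by the SSIM windowing and the Sobel operator.
// [[Rcpp::export]]
arma::mat conv2_valid(const arma::mat& x, const arma::mat& k) {
  const int Ho = x.n_rows - k.n_rows + 1;
  const int Wo = x.n_cols - k.n_cols + 1;
  mat y(Ho, Wo);
  for (int j = 0; j < Wo; ++j)
    for (int i = 0; i < Ho; ++i)
      y(i, j) = accu(x.submat(i, j, i + k.n_rows - 1, j + k.n_cols - 1) % k);
  return y;
}

// Bilinear affine warp: output(r, c) samples input at A %*% (x, y, 1) with
// x = c, y = r in 0-based pixel coordinates; A is 2x3 row-major (a b tx; c d ty).
// Samples outside the input are clamped to the nearest edge pixel.
// [[Rcpp::export]]
arma::cube warp_affine(const arma::cube& img, const arma::mat& A,
                       int outH, int outW) {
  const int H = img.n_rows, W = img.n_cols, C = img.n_slices;
  cube out(outH, outW, C);
  for (int r = 0; r < outH; ++r) {
    for (int c = 0; c < outW; ++c) {
      double sx = A(0, 0) * c + A(0, 1) * r + A(0, 2);
      double sy = A(1, 0) * c + A(1, 1) * r + A(1, 2);
      sx = std::min(std::max(sx, 0.0), (double)(W - 1));
      sy = std::min(std::max(sy, 0.0), (double)(H - 1));
      const int x0 = (int)std::floor(sx), y0 = (int)std::floor(sy);
      const int x1 = std::min(x0 + 1, W - 1), y1 = std::min(y0 + 1, H - 1);
      const double fx = sx - x0, fy = sy - y0;
      for (int ch = 0; ch < C; ++ch)
        out(r, c, ch) =
            (1 - fy) * ((1 - fx) * img(y0, x0, ch) + fx * img(y0, x1, ch)) +
            fy * ((1 - fx) * img(y1, x0, ch) + fx * img(y1, x1, ch));
    }
  }
  return out;
}
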