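// Low-level kernels for the convolutional encoder: im2col/col2im lowering
// (convolutions become one GEMM per layer) and max pooling with argmax
// bookkeeping for the backward pass.
//
// Tensor layout throughout: column-major R arrays with dim (C, H, W, B),
// i.e. element (c, h, w, b) sits at c + C*(h + H*(w + W*b)). With the
// channel index fastest, im2col reads and writes are contiguous in c and
// the convolution output (OC, OH*OW*B) reinterprets as (OC, OH, OW, B)
// without a copy.

#include <Rcpp.h>
#include <limits>
using namespace Rcpp;

static inline int out_size(int n, int k, int s, int p) {
  return (n + 2 * p - k) / s + 1;
}

// Column row order: k = c + C*(ikh + KH*ikw); column order:
// j = oh + OH*(ow + OW*b). Weights must be flattened as (CIN, KH, KW, OC).
// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector x, int kh, int kw, int sh, int sw,
                         int ph, int pw) {
  IntegerVector d = x.attr("dim");
  const int C = d[0], H = d[1], W = d[2], B = d[3];
  const int OH = out_size(H, kh, sh, ph), OW = out_size(W, kw, sw, pw);
  const int K = kh * kw * C;
  const long J = (long)OH * OW * B;
  NumericMatrix cols(K, J);
  const double* px = x.begin();
  double* pc = cols.begin();
  for (int b = 0; b < B; ++b) {
    const double* xb = px + (long)b * C * H * W;
    for (int ow = 0; ow < OW; ++ow) {
      for (int oh = 0; oh < OH; ++oh) {
        double* col = pc + (oh + (long)OH * (ow + (long)OW * b)) * K;
        for (int ikw = 0; ikw < kw; ++ikw) {
          int w = ow * sw - pw + ikw;
          bool win = (w >= 0 && w < W);
          for (int ikh = 0; ikh < kh; ++ikh) {
            int h = oh * sh - ph + ikh;
            double* dst = col + C * (ikh + kh * ikw);
            if (win && h >= 0 && h < H) {
              const double* src = xb + (long)C * (h + (long)H * w);
              for (int c = 0; c < C; ++c) dst[c] = src[c];
            } else {
              for (int c = 0; c < C; ++c) dst[c] = 0.0;
            }
          }
        }
      }
    }
  }
  return cols;
}

// [[Rcpp::export]]
NumericVector col2im_cpp(NumericMatrix cols, IntegerVector xdim, int kh,
                         int kw, int sh, int sw, int ph, int pw) {
  const int C = xdim[0], H = xdim[1], W = xdim[2], B = xdim[3];
  const int OH = out_size(H, kh, sh, ph), OW = out_size(W, kw, sw, pw);
  NumericVector x((long)H * W * C * B);
  x.attr("dim") = xdim;
  double* px = x.begin();
  const double* pc = cols.begin();
  const int K = kh * kw * C;
  for (int b = 0; b < B; ++b) {
    double* xb = px + (long)b * C * H * W;
    for (int ow = 0; ow < OW; ++ow) {
      for (int oh = 0; oh < OH; ++oh) {
        const double* col = pc + (oh + (long)OH * (ow + (long)OW * b)) * K;
        for (int ikw = 0; ikw < kw; ++ikw) {
          int w = ow * sw - pw + ikw;
          if (w < 0 || w >= W) continue;
          for (int ikh = 0; ikh < kh; ++ikh) {
            int h = oh * sh - ph + ikh;
            if (h < 0 || h >= H) continue;
            double* dst = xb + (long)C * (h + (long)H * w);
            const double* src = col + C * (ikh + kh * ikw);
            for (int c = 0; c < C; ++c) dst[c] += src[c];
          }
        }
      }
    }
  }
  return x;
}

// [[Rcpp::export]]
List maxpool_forward_cpp(NumericVector x, int kh, int kw, int sh, int sw,
                         int ph, int pw) {
  IntegerVector d = x.attr("dim");
  const int C = d[0], H = d[1], W = d[2], B = d[3];
  const int OH = out_size(H, kh, sh, ph), OW = out_size(W, kw, sw, pw);
  NumericVector out((long)OH * OW * C * B);
  IntegerVector arg((long)OH * OW * C * B);
  out.attr("dim") = IntegerVector::create(C, OH, OW, B);
  const double* px = x.begin();
  double* po = out.begin();
  int* pa = arg.begin();
  const double ninf = -std::numeric_limits<double>::infinity();
  for (int b = 0; b < B; ++b) {
    const long xb = (long)b * C * H * W;
    for (int ow = 0; ow < OW; ++ow) {
      for (int oh = 0; oh < OH; ++oh) {
        long obase = (long)C * (oh + (long)OH * (ow + (long)OW * b));
        for (int c = 0; c < C; ++c) { po[obase + c] = ninf; pa[obase + c] = -1; }
        for (int ikw = 0; ikw < kw; ++ikw) {
          int w = ow * sw - pw + ikw;
          if (w < 0 || w >= W) continue;
          for (int ikh = 0; ikh < kh; ++ikh) {
            int h = oh * sh - ph + ikh;
            if (h < 0 || h >= H) continue;
            const double* src = px + xb + (long)C * (h + (long)H * w);
            for (int c = 0; c < C; ++c) {
              if (src[c] > po[obase + c]) {
                po[obase + c] = src[c];
                pa[obase + c] = (int)(xb + (long)C * (h + (long)H * w) + c);
              }
            }
          }
        }
      }
    }
  }
  return List::create(_["out"] = out, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector maxpool_backward_cpp(NumericVector dout, IntegerVector argmax,
                                   IntegerVector xdim) {
  NumericVector dx((long)xdim[0] * xdim[1] * xdim[2] * xdim[3]);
  dx.attr("dim") = xdim;
  double* pdx = dx.begin();
  const double* pd = dout.begin();
  const int* pa = argmax.begin();
  const long n = dout.size();
  for (long i = 0; i < n; ++i) pdx[pa[i]] += pd[i];
  return dx;
}
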