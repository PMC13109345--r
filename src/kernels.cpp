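#include <Rcpp.h>
using namespace Rcpp;

// Tensors use channel-first layout: element (c, h, w) of a C x H x W map sits
// at linear index c + C*h + C*H*w (0-based).  im2col unrolls every receptive
// field into one column so the convolution itself becomes a single GEMM done
// with R's BLAS; rows are ordered channel-fastest, then kernel row, then
// kernel column, and columns are ordered output-row-fastest.

// [[Rcpp::export]]
NumericMatrix im2col_chw(const NumericVector& x, int C, int H, int W,
                         int kh, int kw, int stride,
                         int pad_top, int pad_left, int oh, int ow) {
  NumericMatrix cols(C * kh * kw, oh * ow);
  double* out = cols.begin();
  const double* in = x.begin();
  for (int owi = 0; owi < ow; ++owi) {
    for (int ohi = 0; ohi < oh; ++ohi) {
      double* colp = out + (std::size_t)(ohi + oh * owi) * C * kh * kw;
      for (int n = 0; n < kw; ++n) {
        int wi = owi * stride - pad_left + n;
        for (int m = 0; m < kh; ++m) {
          int hi = ohi * stride - pad_top + m;
          double* dst = colp + C * (m + kh * n);
          if (hi < 0 || hi >= H || wi < 0 || wi >= W) {
            for (int c = 0; c < C; ++c) dst[c] = 0.0;
          } else {
            const double* src = in + C * (hi + H * wi);
            for (int c = 0; c < C; ++c) dst[c] = src[c];
          }
        }
      }
    }
  }
  return cols;
}

// Adjoint of im2col: scatter-add column gradients back onto the input map.
// [[Rcpp::export]]
NumericVector col2im_chw(const NumericMatrix& cols, int C, int H, int W,
                         int kh, int kw, int stride,
                         int pad_top, int pad_left, int oh, int ow) {
  NumericVector x(C * H * W);
  double* out = x.begin();
  const double* in = cols.begin();
  for (int owi = 0; owi < ow; ++owi) {
    for (int ohi = 0; ohi < oh; ++ohi) {
      const double* colp = in + (std::size_t)(ohi + oh * owi) * C * kh * kw;
      for (int n = 0; n < kw; ++n) {
        int wi = owi * stride - pad_left + n;
        if (wi < 0 || wi >= W) continue;
        for (int m = 0; m < kh; ++m) {
          int hi = ohi * stride - pad_top + m;
          if (hi < 0 || hi >= H) continue;
          const double* src = colp + C * (m + kh * n);
          double* dst = out + C * (hi + H * wi);
          for (int c = 0; c < C; ++c) dst[c] += src[c];
        }
      }
    }
  }
  return x;
}

// Valid max pooling; also emits the 1-based argmax index of every output
// element so the backward pass can scatter gradients to the winners.
// [[Rcpp::export]]
List maxpool_chw(const NumericVector& x, int C, int H, int W,
                 int k, int stride) {
  int oh = (H - k) / stride + 1;
  int ow = (W - k) / stride + 1;
  NumericVector y(C * oh * ow);
  IntegerVector arg(C * oh * ow);
  const double* in = x.begin();
  for (int owi = 0; owi < ow; ++owi) {
    for (int ohi = 0; ohi < oh; ++ohi) {
      for (int c = 0; c < C; ++c) {
        double best = R_NegInf;
        int besti = -1;
        for (int n = 0; n < k; ++n) {
          int wi = owi * stride + n;
          for (int m = 0; m < k; ++m) {
            int hi = ohi * stride + m;
            int idx = c + C * (hi + H * wi);
            if (in[idx] > best) { best = in[idx]; besti = idx; }
          }
        }
        int oidx = c + C * (ohi + oh * owi);
        y[oidx] = best;
        arg[oidx] = besti + 1;
      }
    }
  }
  return List::create(_["values"] = y, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector maxpool_backward_chw(const IntegerVector& argmax,
                                   const NumericVector& dy, int n_in) {
  NumericVector dx(n_in);
  for (int i = 0; i < argmax.size(); ++i) dx[argmax[i] - 1] += dy[i];
  return dx;
}
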