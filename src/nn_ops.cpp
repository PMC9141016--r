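#include <Rcpp.h>
using namespace Rcpp;

// Layout convention: a batch of B sequences of length L with C channels is a
// (B*L) x C numeric matrix whose row (b-1)*L + l holds position l of sample b.

// im2col for 1-D convolution with "same" zero padding and odd kernel width W.
// Output: (B*L) x (W*C); column (w-1)*C + c holds channel c at offset
// w - (W+1)/2 relative to each position, zero outside the sample.
// [[Rcpp::export]]
NumericMatrix im2col_1d(const NumericMatrix& x, int B, int L, int W) {
  const int C = x.ncol();
  const int half = (W - 1) / 2;
  NumericMatrix out(B * L, W * C);
  for (int w = 0; w < W; ++w) {
    const int off = w - half;
    for (int c = 0; c < C; ++c) {
      const int oc = w * C + c;
      for (int b = 0; b < B; ++b) {
        const int base = b * L;
        int l0 = std::max(0, -off);
        int l1 = std::min(L, L - off);
        for (int l = l0; l < l1; ++l) {
          out(base + l, oc) = x(base + l + off, c);
        }
      }
    }
  }
  return out;
}

// Adjoint of im2col_1d: scatter-add gradient columns back onto positions.
// [[Rcpp::export]]
NumericMatrix col2im_1d(const NumericMatrix& dcol, int B, int L, int W, int C) {
  const int half = (W - 1) / 2;
  NumericMatrix out(B * L, C);
  for (int w = 0; w < W; ++w) {
    const int off = w - half;
    for (int c = 0; c < C; ++c) {
      const int oc = w * C + c;
      for (int b = 0; b < B; ++b) {
        const int base = b * L;
        int l0 = std::max(0, -off);
        int l1 = std::min(L, L - off);
        for (int l = l0; l < l1; ++l) {
          out(base + l + off, c) += dcol(base + l, oc);
        }
      }
    }
  }
  return out;
}

// 1-D max pooling, window `win`, stride `stride` (valid: trailing positions
// that do not fill a window are dropped, matching the usual framework
// default). Returns the pooled matrix and 1-based argmax row indices into
// the input, for the backward pass.
// [[Rcpp::export]]
List maxpool_1d(const NumericMatrix& x, int B, int L, int win, int stride) {
  const int C = x.ncol();
  const int Lp = (L - win) / stride + 1;
  if (Lp < 1) stop("maxpool_1d: pooled length < 1 (L=%d, window=%d)", L, win);
  NumericMatrix out(B * Lp, C);
  IntegerMatrix arg(B * Lp, C);
  for (int b = 0; b < B; ++b) {
    for (int p = 0; p < Lp; ++p) {
      const int start = b * L + p * stride;
      const int orow = b * Lp + p;
      for (int c = 0; c < C; ++c) {
        double best = x(start, c);
        int besti = start;
        for (int k = 1; k < win; ++k) {
          const double v = x(start + k, c);
          if (v > best) { best = v; besti = start + k; }
        }
        out(orow, c) = best;
        arg(orow, c) = besti + 1;  // 1-based for R
      }
    }
  }
  return List::create(_["out"] = out, _["argmax"] = arg);
}

// Backward of maxpool_1d: route gradients to the argmax positions.
// [[Rcpp::export]]
NumericMatrix maxpool_1d_backward(const NumericMatrix& dy,
                                  const IntegerMatrix& argmax,
                                  int BL_in) {
  const int C = dy.ncol();
  NumericMatrix out(BL_in, C);
  for (int c = 0; c < C; ++c) {
    for (int r = 0; r < dy.nrow(); ++r) {
      out(argmax(r, c) - 1, c) += dy(r, c);
    }
  }
  return out;
}
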