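// Low-level CPU kernels for the network layers.
// Array layout everywhere: column-major R arrays, dims (H, W, C, N):
// index = h + H*w + H*W*c + H*W*C*n.  Weight layout: (kh, kw, Cin, Cout).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int out_size(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

// Fill `col` (kh*kw*C x Hout*Wout) from one sample; row k = ki + kh*(kj + kw*c),
// column p = ho + Hout*wo.  Out-of-bounds taps are zero (zero padding).
static void im2col(const double* x, int H, int W, int C,
                   int kh, int kw, int stride, int pad,
                   int Hout, int Wout, arma::mat& col) {
  col.zeros();
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)H * W * c;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int krow = ki + kh * (kj + kw * c);
        for (int wo = 0; wo < Wout; ++wo) {
          const int wi = wo * stride - pad + kj;
          if (wi < 0 || wi >= W) continue;
          const double* xcol = xc + (size_t)H * wi;
          double* cptr = col.memptr() + (size_t)krow + (size_t)col.n_rows * ((size_t)Hout * wo);
          for (int ho = 0; ho < Hout; ++ho) {
            const int hi = ho * stride - pad + ki;
            if (hi < 0 || hi >= H) continue;
            cptr[(size_t)col.n_rows * ho] = xcol[hi];
          }
        }
      }
    }
  }
}

// Scatter-add the columns back into one sample's gradient (reverse of im2col).
static void col2im(const arma::mat& col, int H, int W, int C,
                   int kh, int kw, int stride, int pad,
                   int Hout, int Wout, double* gx) {
  for (int c = 0; c < C; ++c) {
    double* xc = gx + (size_t)H * W * c;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int krow = ki + kh * (kj + kw * c);
        for (int wo = 0; wo < Wout; ++wo) {
          const int wi = wo * stride - pad + kj;
          if (wi < 0 || wi >= W) continue;
          double* xcol = xc + (size_t)H * wi;
          const double* cptr = col.memptr() + (size_t)krow + (size_t)col.n_rows * ((size_t)Hout * wo);
          for (int ho = 0; ho < Hout; ++ho) {
            const int hi = ho * stride - pad + ki;
            if (hi < 0 || hi >= H) continue;
            xcol[hi] += cptr[(size_t)col.n_rows * ho];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector nn_conv2d_fwd(NumericVector x, NumericVector w, NumericVector b,
                            int stride, int pad) {
  IntegerVector dx = x.attr("dim"), dw = w.attr("dim");
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  const int kh = dw[0], kw = dw[1], Cin = dw[2], Cout = dw[3];
  if (Cin != C) stop("conv2d: input has %d channels but weights expect %d", C, Cin);
  const int Hout = out_size(H, kh, stride, pad), Wout = out_size(W, kw, stride, pad);
  if (Hout <= 0 || Wout <= 0) stop("conv2d: output size would be non-positive");
  const int K = kh * kw * C, P = Hout * Wout;

  NumericVector y((size_t)Hout * Wout * Cout * N);
  y.attr("dim") = IntegerVector::create(Hout, Wout, Cout, N);
  arma::mat Wm(w.begin(), K, Cout, false, true);
  arma::rowvec bv(b.begin(), Cout);
  arma::mat col(K, P);

  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)H * W * C * n, H, W, C, kh, kw, stride, pad, Hout, Wout, col);
    arma::mat Y(y.begin() + (size_t)Hout * Wout * Cout * n, P, Cout, false, true);
    Y = col.t() * Wm;
    Y.each_row() += bv;
  }
  return y;
}

// [[Rcpp::export]]
List nn_conv2d_bwd(NumericVector x, NumericVector w, NumericVector gy,
                   int stride, int pad) {
  IntegerVector dx = x.attr("dim"), dw = w.attr("dim"), dy = gy.attr("dim");
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  const int kh = dw[0], kw = dw[1], Cout = dw[3];
  const int Hout = dy[0], Wout = dy[1];
  const int K = kh * kw * C, P = Hout * Wout;

  NumericVector gx((size_t)H * W * C * N), gw(w.size()), gb(Cout);
  gx.attr("dim") = dx;
  gw.attr("dim") = dw;
  arma::mat Wm(w.begin(), K, Cout, false, true);
  arma::mat GW(gw.begin(), K, Cout, false, true);
  arma::vec GB(gb.begin(), Cout, false, true);
  arma::mat col(K, P);

  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)H * W * C * n, H, W, C, kh, kw, stride, pad, Hout, Wout, col);
    arma::mat G(gy.begin() + (size_t)P * Cout * n, P, Cout, false, true);
    GW += col * G;
    GB += arma::sum(G, 0).t();
    arma::mat gcol = Wm * G.t();  // K x P
    col2im(gcol, H, W, C, kh, kw, stride, pad, Hout, Wout,
           gx.begin() + (size_t)H * W * C * n);
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// 2x2 max pooling, stride 2.  Returns pooled values and the linear (1-based)
// argmax index into the input array, for the backward pass.
// [[Rcpp::export]]
List nn_maxpool2_fwd(NumericVector x) {
  IntegerVector dx = x.attr("dim");
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  if (H % 2 || W % 2) stop("maxpool2: spatial size must be even, got %dx%d", H, W);
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((size_t)Ho * Wo * C * N);
  IntegerVector idx((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);

  size_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t base = (size_t)H * W * ((size_t)c + (size_t)C * n);
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          const int hi = 2 * ho, wi = 2 * wo;
          size_t best = base + hi + (size_t)H * wi;
          double bv = x[best];
          const size_t cand[3] = {base + hi + 1 + (size_t)H * wi,
                                  base + hi + (size_t)H * (wi + 1),
                                  base + hi + 1 + (size_t)H * (wi + 1)};
          for (int t = 0; t < 3; ++t)
            if (x[cand[t]] > bv) { bv = x[cand[t]]; best = cand[t]; }
          y[o] = bv;
          idx[o] = (int)(best + 1);
          ++o;
        }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector nn_maxpool2_bwd(NumericVector gy, IntegerVector idx, IntegerVector dimx) {
  NumericVector gx((size_t)dimx[0] * dimx[1] * dimx[2] * dimx[3]);
  gx.attr("dim") = dimx;
  for (R_xlen_t i = 0; i < gy.size(); ++i) gx[idx[i] - 1] += gy[i];
  return gx;
}

// Bilinear interpolation weights for one output axis (half-pixel centres).
static void bil_taps(int out, int in, double scale, std::vector<int>& i0,
                     std::vector<int>& i1, std::vector<double>& w1) {
  i0.resize(out); i1.resize(out); w1.resize(out);
  for (int i = 0; i < out; ++i) {
    double src = (i + 0.5) * scale - 0.5;
    int lo = (int)std::floor(src);
    double f = src - lo;
    if (lo < 0) { lo = 0; f = 0.0; }
    int hi = lo + 1;
    if (hi > in - 1) { hi = in - 1; if (lo > in - 1) lo = in - 1; f = 0.0; }
    i0[i] = lo; i1[i] = hi; w1[i] = f;
  }
}

// [[Rcpp::export]]
NumericVector nn_upsample2_fwd(NumericVector x) {
  IntegerVector dx = x.attr("dim");
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  const int Ho = 2 * H, Wo = 2 * W;
  std::vector<int> h0, h1, w0, w1v; std::vector<double> hf, wf;
  bil_taps(Ho, H, 0.5, h0, h1, hf);
  bil_taps(Wo, W, 0.5, w0, w1v, wf);
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  size_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + (size_t)H * W * ((size_t)c + (size_t)C * n);
      for (int wo = 0; wo < Wo; ++wo) {
        const double* cl = xc + (size_t)H * w0[wo];
        const double* ch = xc + (size_t)H * w1v[wo];
        const double fw = wf[wo];
        for (int ho = 0; ho < Ho; ++ho) {
          const double fh = hf[ho];
          y[o++] = (1 - fh) * ((1 - fw) * cl[h0[ho]] + fw * ch[h0[ho]]) +
                   fh * ((1 - fw) * cl[h1[ho]] + fw * ch[h1[ho]]);
        }
      }
    }
  return y;
}

// [[Rcpp::export]]
NumericVector nn_upsample2_bwd(NumericVector gy, IntegerVector dimx) {
  const int H = dimx[0], W = dimx[1], C = dimx[2], N = dimx[3];
  const int Ho = 2 * H, Wo = 2 * W;
  std::vector<int> h0, h1, w0, w1v; std::vector<double> hf, wf;
  bil_taps(Ho, H, 0.5, h0, h1, hf);
  bil_taps(Wo, W, 0.5, w0, w1v, wf);
  NumericVector gx((size_t)H * W * C * N);
  gx.attr("dim") = dimx;
  size_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double* xc = gx.begin() + (size_t)H * W * ((size_t)c + (size_t)C * n);
      for (int wo = 0; wo < Wo; ++wo) {
        double* cl = xc + (size_t)H * w0[wo];
        double* ch = xc + (size_t)H * w1v[wo];
        const double fw = wf[wo];
        for (int ho = 0; ho < Ho; ++ho) {
          const double g = gy[o++], fh = hf[ho];
          cl[h0[ho]] += (1 - fh) * (1 - fw) * g;
          ch[h0[ho]] += (1 - fh) * fw * g;
          cl[h1[ho]] += fh * (1 - fw) * g;
          ch[h1[ho]] += fh * fw * g;
        }
      }
    }
  return gx;
}

// General bilinear resize of an (H, W, C) image to (oh, ow); used by data I/O,
// not by the autograd graph.
// [[Rcpp::export]]
NumericVector nn_resize_bilinear(NumericVector x, int oh, int ow) {
  IntegerVector dx = x.attr("dim");
  const int H = dx[0], W = dx[1], C = dx[2];
  std::vector<int> h0, h1, w0, w1v; std::vector<double> hf, wf;
  bil_taps(oh, H, (double)H / oh, h0, h1, hf);
  bil_taps(ow, W, (double)W / ow, w0, w1v, wf);
  NumericVector y((size_t)oh * ow * C);
  y.attr("dim") = IntegerVector::create(oh, ow, C);
  size_t o = 0;
  for (int c = 0; c < C; ++c) {
    const double* xc = x.begin() + (size_t)H * W * c;
    for (int wo = 0; wo < ow; ++wo) {
      const double* cl = xc + (size_t)H * w0[wo];
      const double* ch = xc + (size_t)H * w1v[wo];
      const double fw = wf[wo];
      for (int ho = 0; ho < oh; ++ho) {
        const double fh = hf[ho];
        y[o++] = (1 - fh) * ((1 - fw) * cl[h0[ho]] + fw * ch[h0[ho]]) +
                 fh * ((1 - fw) * cl[h1[ho]] + fw * ch[h1[ho]]);
      }
    }
  }
  return y;
}
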