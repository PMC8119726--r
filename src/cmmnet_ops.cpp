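// Low-level tensor kernels for the segmentation networks.
//
// Tensor layout follows R's column-major array convention throughout:
// feature maps are (H, W, C, N) numeric arrays, kernels are
// (kh, kw, Cin, Cout).  All convolutions are cross-correlations with
// zero padding chosen so the spatial output size equals the input size
// for every dilation rate (pad = rate * (k - 1) / 2, odd kernels only).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static void dims4(const NumericVector& x, int& H, int& W, int& C, int& N) {
  IntegerVector d = x.attr("dim");
  H = d[0];
  W = d[1];
  C = d.size() > 2 ? d[2] : 1;
  N = d.size() > 3 ? d[3] : 1;
}

// Fill the im2col matrix M (kh*kw*Cin x H*W) for one sample.
static void im2col(const double* x, int H, int W, int C, int kh, int kw,
                   int rate, arma::mat& M) {
  const int ch = (kh - 1) / 2, cw = (kw - 1) / 2;
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)H * W * c;
    for (int v = 0; v < kw; ++v) {
      for (int u = 0; u < kh; ++u) {
        const int row = u + kh * (v + kw * c);
        const int du = rate * (u - ch), dv = rate * (v - cw);
        for (int j = 0; j < W; ++j) {
          const int jj = j + dv;
          if (jj < 0 || jj >= W) {
            for (int i = 0; i < H; ++i)
              M((size_t)row, (size_t)i + (size_t)H * j) = 0.0;
            continue;
          }
          for (int i = 0; i < H; ++i) {
            const int ii = i + du;
            M((size_t)row, (size_t)i + (size_t)H * j) =
              (ii < 0 || ii >= H) ? 0.0 : xc[ii + H * jj];
          }
        }
      }
    }
  }
}

// Scatter-add columns of D (kh*kw*Cin x H*W) back onto the input grid.
static void col2im(const arma::mat& D, int H, int W, int C, int kh, int kw,
                   int rate, double* dx) {
  const int ch = (kh - 1) / 2, cw = (kw - 1) / 2;
  for (int c = 0; c < C; ++c) {
    double* xc = dx + (size_t)H * W * c;
    for (int v = 0; v < kw; ++v) {
      for (int u = 0; u < kh; ++u) {
        const int row = u + kh * (v + kw * c);
        const int du = rate * (u - ch), dv = rate * (v - cw);
        for (int j = 0; j < W; ++j) {
          const int jj = j + dv;
          if (jj < 0 || jj >= W) continue;
          for (int i = 0; i < H; ++i) {
            const int ii = i + du;
            if (ii < 0 || ii >= H) continue;
            xc[ii + H * jj] += D((size_t)row, (size_t)i + (size_t)H * j);
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericVector w,
                             Nullable<NumericVector> bias, int rate) {
  int H, W, C, N;
  dims4(x, H, W, C, N);
  IntegerVector wd = w.attr("dim");
  const int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("conv2d: input has %d channels, kernel expects %d", C, Cin);
  if (kh % 2 == 0 || kw % 2 == 0) stop("conv2d: kernel dims must be odd");
  if (rate < 1) stop("conv2d: dilation rate must be >= 1");

  NumericVector y((size_t)H * W * Cout * N);
  y.attr("dim") = IntegerVector::create(H, W, Cout, N);
  arma::mat Wm(const_cast<double*>(w.begin()), (size_t)kh * kw * Cin, Cout,
               false, true);
  arma::mat M((size_t)kh * kw * Cin, (size_t)H * W);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)H * W * C * n, H, W, C, kh, kw, rate, M);
    arma::mat Y = M.t() * Wm;  // (H*W x Cout)
    double* yp = y.begin() + (size_t)H * W * Cout * n;
    std::copy(Y.begin(), Y.end(), yp);
    if (bias.isNotNull()) {
      NumericVector b(bias);
      for (int co = 0; co < Cout; ++co) {
        double* yc = yp + (size_t)H * W * co;
        const double bc = b[co];
        for (size_t p = 0; p < (size_t)H * W; ++p) yc[p] += bc;
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, NumericVector w, NumericVector dy,
                    int rate, bool has_bias) {
  int H, W, C, N;
  dims4(x, H, W, C, N);
  IntegerVector wd = w.attr("dim");
  const int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];

  NumericVector dx(x.size());
  dx.attr("dim") = x.attr("dim");
  NumericVector dw(w.size());
  dw.attr("dim") = w.attr("dim");
  NumericVector db(Cout);

  arma::mat Wm(const_cast<double*>(w.begin()), (size_t)kh * kw * Cin, Cout,
               false, true);
  arma::mat dWm(dw.begin(), (size_t)kh * kw * Cin, Cout, false, true);
  arma::mat M((size_t)kh * kw * Cin, (size_t)H * W);
  for (int n = 0; n < N; ++n) {
    arma::mat DY(const_cast<double*>(dy.begin()) + (size_t)H * W * Cout * n,
                 (size_t)H * W, Cout, false, true);
    im2col(x.begin() + (size_t)H * W * C * n, H, W, C, kh, kw, rate, M);
    dWm += M * DY;
    arma::mat DX = Wm * DY.t();  // (kh*kw*Cin x H*W)
    col2im(DX, H, W, C, kh, kw, rate, dx.begin() + (size_t)H * W * C * n);
    if (has_bias)
      for (int co = 0; co < Cout; ++co)
        db[co] += arma::accu(DY.col(co));
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// 2x2 max pooling, stride 2.  Records flat argmax indices (0-based into x).
// [[Rcpp::export]]
List cpp_maxpool2_fwd(NumericVector x) {
  int H, W, C, N;
  dims4(x, H, W, C, N);
  if (H % 2 || W % 2) stop("maxpool2: spatial dims must be even");
  const int oh = H / 2, ow = W / 2;
  NumericVector y((size_t)oh * ow * C * N);
  y.attr("dim") = IntegerVector::create(oh, ow, C, N);
  IntegerVector idx(y.size());
  size_t q = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t base = (size_t)H * W * (c + (size_t)C * n);
      for (int j = 0; j < ow; ++j)
        for (int i = 0; i < oh; ++i) {
          size_t best = base + (size_t)(2 * i) + (size_t)H * (2 * j);
          double bv = x[best];
          const int di[3] = {1, 0, 1}, dj[3] = {0, 1, 1};
          for (int t = 0; t < 3; ++t) {
            size_t p = base + (size_t)(2 * i + di[t]) + (size_t)H * (2 * j + dj[t]);
            if (x[p] > bv) { bv = x[p]; best = p; }
          }
          // y is filled column-major in (oh,ow) order per channel: position
          const size_t yo = (size_t)i + (size_t)oh * j +
                            (size_t)oh * ow * (c + (size_t)C * n);
          y[yo] = bv;
          idx[yo] = (int)best;
          ++q;
        }
    }
  (void)q;
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_bwd(IntegerVector idx, NumericVector dy,
                               IntegerVector xdim) {
  size_t len = 1;
  for (int i = 0; i < xdim.size(); ++i) len *= (size_t)xdim[i];
  NumericVector dx(len);
  dx.attr("dim") = xdim;
  for (R_xlen_t p = 0; p < dy.size(); ++p) dx[idx[p]] += dy[p];
  return dx;
}

static inline void bin_bounds(int o, int In, int Out, int& s, int& e) {
  s = (int)std::floor((double)o * In / Out);
  e = (int)std::ceil((double)(o + 1) * In / Out);
  if (e > In) e = In;
  if (e <= s) e = s + 1;
}

// Adaptive average pooling to (oh, ow) with floor/ceil bin edges.
// [[Rcpp::export]]
NumericVector cpp_adaptive_avgpool_fwd(NumericVector x, int oh, int ow) {
  int H, W, C, N;
  dims4(x, H, W, C, N);
  NumericVector y((size_t)oh * ow * C * N);
  y.attr("dim") = IntegerVector::create(oh, ow, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + (size_t)H * W * (c + (size_t)C * n);
      double* yc = y.begin() + (size_t)oh * ow * (c + (size_t)C * n);
      for (int j = 0; j < ow; ++j) {
        int js, je; bin_bounds(j, W, ow, js, je);
        for (int i = 0; i < oh; ++i) {
          int is, ie; bin_bounds(i, H, oh, is, ie);
          double s = 0.0;
          for (int jj = js; jj < je; ++jj)
            for (int ii = is; ii < ie; ++ii) s += xc[ii + H * jj];
          yc[i + oh * j] = s / ((ie - is) * (je - js));
        }
      }
    }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_adaptive_avgpool_bwd(NumericVector dy, int H, int W) {
  int oh, ow, C, N;
  dims4(dy, oh, ow, C, N);
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double* xc = dx.begin() + (size_t)H * W * (c + (size_t)C * n);
      const double* yc = dy.begin() + (size_t)oh * ow * (c + (size_t)C * n);
      for (int j = 0; j < ow; ++j) {
        int js, je; bin_bounds(j, W, ow, js, je);
        for (int i = 0; i < oh; ++i) {
          int is, ie; bin_bounds(i, H, oh, is, ie);
          const double g = yc[i + oh * j] / ((ie - is) * (je - js));
          for (int jj = js; jj < je; ++jj)
            for (int ii = is; ii < ie; ++ii) xc[ii + H * jj] += g;
        }
      }
    }
  return dx;
}

struct LinW { int i0, i1; double f; };

static void lin_weights(int In, int Out, std::vector<LinW>& w) {
  // half-pixel centers, align_corners = false
  w.resize(Out);
  for (int o = 0; o < Out; ++o) {
    double s = ((double)o + 0.5) * In / Out - 0.5;
    if (s < 0) s = 0;
    int i0 = (int)std::floor(s);
    double f = s - i0;
    int i1 = i0 + 1;
    if (i1 >= In) { i1 = In - 1; if (i0 >= In - 1) { i0 = In - 1; f = 0.0; } }
    w[o] = {i0, i1, f};
  }
}

// Bilinear resampling to (oh, ow).
// [[Rcpp::export]]
NumericVector cpp_bilinear_fwd(NumericVector x, int oh, int ow) {
  int H, W, C, N;
  dims4(x, H, W, C, N);
  std::vector<LinW> wi, wj;
  lin_weights(H, oh, wi);
  lin_weights(W, ow, wj);
  NumericVector y((size_t)oh * ow * C * N);
  y.attr("dim") = IntegerVector::create(oh, ow, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + (size_t)H * W * (c + (size_t)C * n);
      double* yc = y.begin() + (size_t)oh * ow * (c + (size_t)C * n);
      for (int j = 0; j < ow; ++j) {
        const LinW& b = wj[j];
        for (int i = 0; i < oh; ++i) {
          const LinW& a = wi[i];
          yc[i + oh * j] =
            (1 - a.f) * (1 - b.f) * xc[a.i0 + H * b.i0] +
            a.f * (1 - b.f) * xc[a.i1 + H * b.i0] +
            (1 - a.f) * b.f * xc[a.i0 + H * b.i1] +
            a.f * b.f * xc[a.i1 + H * b.i1];
        }
      }
    }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_bilinear_bwd(NumericVector dy, int H, int W) {
  int oh, ow, C, N;
  dims4(dy, oh, ow, C, N);
  std::vector<LinW> wi, wj;
  lin_weights(H, oh, wi);
  lin_weights(W, ow, wj);
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double* xc = dx.begin() + (size_t)H * W * (c + (size_t)C * n);
      const double* yc = dy.begin() + (size_t)oh * ow * (c + (size_t)C * n);
      for (int j = 0; j < ow; ++j) {
        const LinW& b = wj[j];
        for (int i = 0; i < oh; ++i) {
          const LinW& a = wi[i];
          const double g = yc[i + oh * j];
          xc[a.i0 + H * b.i0] += (1 - a.f) * (1 - b.f) * g;
          xc[a.i1 + H * b.i0] += a.f * (1 - b.f) * g;
          xc[a.i0 + H * b.i1] += (1 - a.f) * b.f * g;
          xc[a.i1 + H * b.i1] += a.f * b.f * g;
        }
      }
    }
  return dx;
}
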