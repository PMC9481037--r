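// Low-level tensor kernels for stride-1 padded convolution, non-overlapping
// transposed convolution (kernel == stride) and 2x2-style max pooling.
// Array layout everywhere: (H, W, C, N), column-major, sample-contiguous.
// Convolutions are decomposed per kernel offset (dy, dx) into dense GEMMs so
// peak memory stays at one (H*W x C) scratch matrix instead of a full im2col.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline Dimension dim4(int a, int b, int c, int d) {
  return Dimension(IntegerVector::create(a, b, c, d));
}

static inline IntegerVector dims_of(const NumericVector& a) {
  return a.attr("dim");
}

// weight layout: (k, k, Cin, Cout); index (dy, dx, c, o)
static arma::mat weight_slice(const NumericVector& w, int k, int Cin, int Cout,
                              int dy, int dx) {
  arma::mat Wm(Cin, Cout);
  const double* p = w.begin();
  for (int o = 0; o < Cout; ++o)
    for (int c = 0; c < Cin; ++c)
      Wm(c, o) = p[dy + k * (dx + k * (c + (size_t)Cin * o))];
  return Wm;
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericVector w,
                             NumericVector b, int pad) {
  IntegerVector dx_ = dims_of(x), dw_ = dims_of(w);
  int H = dx_[0], W = dx_[1], C = dx_[2], N = dx_[3];
  int k = dw_[0], Cout = dw_[3];
  int Ho = H + 2 * pad - k + 1, Wo = W + 2 * pad - k + 1;
  NumericVector out(dim4(Ho, Wo, Cout, N));
  size_t xs = (size_t)H * W * C, ys = (size_t)Ho * Wo * Cout;
  for (int n = 0; n < N; ++n) {
    arma::cube X(const_cast<double*>(x.begin()) + n * xs, H, W, C, false, true);
    arma::cube Y(out.begin() + n * ys, Ho, Wo, Cout, false, true);
    for (int o = 0; o < Cout; ++o) Y.slice(o).fill(b[o]);
    for (int dy = 0; dy < k; ++dy) {
      for (int dxk = 0; dxk < k; ++dxk) {
        int ho1 = std::max(0, pad - dy), ho2 = std::min(Ho - 1, H - 1 + pad - dy);
        int wo1 = std::max(0, pad - dxk), wo2 = std::min(Wo - 1, W - 1 + pad - dxk);
        if (ho1 > ho2 || wo1 > wo2) continue;
        int nh = ho2 - ho1 + 1, nw = wo2 - wo1 + 1;
        int hi1 = ho1 + dy - pad, wi1 = wo1 + dxk - pad;
        arma::mat Xm(nh * nw, C);
        for (int c = 0; c < C; ++c)
          Xm.col(c) = arma::vectorise(
              X.slice(c).submat(hi1, wi1, hi1 + nh - 1, wi1 + nw - 1));
        arma::mat Ym = Xm * weight_slice(w, k, C, Cout, dy, dxk);
        for (int o = 0; o < Cout; ++o)
          Y.slice(o).submat(ho1, wo1, ho2, wo2) +=
              arma::reshape(Ym.col(o), nh, nw);
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, NumericVector w, NumericVector gy,
                    int pad) {
  IntegerVector dx_ = dims_of(x), dw_ = dims_of(w), dg_ = dims_of(gy);
  int H = dx_[0], W = dx_[1], C = dx_[2], N = dx_[3];
  int k = dw_[0], Cout = dw_[3];
  int Ho = dg_[0], Wo = dg_[1];
  NumericVector gx(dim4(H, W, C, N));
  NumericVector gw(dim4(k, k, C, Cout));
  NumericVector gb(Cout);
  size_t xs = (size_t)H * W * C, ys = (size_t)Ho * Wo * Cout;
  arma::cube GW(gw.begin(), (size_t)k * k, C, Cout, false, true); // (kk, C, O)
  for (int n = 0; n < N; ++n) {
    arma::cube X(const_cast<double*>(x.begin()) + n * xs, H, W, C, false, true);
    arma::cube GX(gx.begin() + n * xs, H, W, C, false, true);
    arma::cube GY(const_cast<double*>(gy.begin()) + n * ys, Ho, Wo, Cout, false,
                  true);
    for (int o = 0; o < Cout; ++o) gb[o] += arma::accu(GY.slice(o));
    for (int dy = 0; dy < k; ++dy) {
      for (int dxk = 0; dxk < k; ++dxk) {
        int ho1 = std::max(0, pad - dy), ho2 = std::min(Ho - 1, H - 1 + pad - dy);
        int wo1 = std::max(0, pad - dxk), wo2 = std::min(Wo - 1, W - 1 + pad - dxk);
        if (ho1 > ho2 || wo1 > wo2) continue;
        int nh = ho2 - ho1 + 1, nw = wo2 - wo1 + 1;
        int hi1 = ho1 + dy - pad, wi1 = wo1 + dxk - pad;
        arma::mat Xm(nh * nw, C), Gm(nh * nw, Cout);
        for (int c = 0; c < C; ++c)
          Xm.col(c) = arma::vectorise(
              X.slice(c).submat(hi1, wi1, hi1 + nh - 1, wi1 + nw - 1));
        for (int o = 0; o < Cout; ++o)
          Gm.col(o) = arma::vectorise(
              GY.slice(o).submat(ho1, wo1, ho2, wo2));
        arma::mat dWm = Xm.t() * Gm; // C x O
        for (int o = 0; o < Cout; ++o)
          for (int c = 0; c < C; ++c)
            GW(dy + k * dxk, c, o) += dWm(c, o);
        arma::mat dXm = Gm * weight_slice(w, k, C, Cout, dy, dxk).t();
        for (int c = 0; c < C; ++c)
          GX.slice(c).submat(hi1, wi1, hi1 + nh - 1, wi1 + nw - 1) +=
              arma::reshape(dXm.col(c), nh, nw);
      }
    }
  }
  return List::create(Named("gx") = gx, Named("gw") = gw, Named("gb") = gb);
}

// Transposed convolution restricted to kernel == stride (no output overlap):
// y(h*s+dy, w*s+dx, o) = sum_c x(h,w,c) * W(dy,dx,c,o) + b(o)
// [[Rcpp::export]]
NumericVector cpp_convT_fwd(NumericVector x, NumericVector w, NumericVector b,
                            int stride) {
  IntegerVector dx_ = dims_of(x), dw_ = dims_of(w);
  int H = dx_[0], W = dx_[1], C = dx_[2], N = dx_[3];
  int k = dw_[0], Cout = dw_[3];
  if (k != stride) stop("cpp_convT_fwd: kernel must equal stride");
  int Ho = H * stride, Wo = W * stride;
  NumericVector out(dim4(Ho, Wo, Cout, N));
  size_t xs = (size_t)H * W * C, ys = (size_t)Ho * Wo * Cout;
  for (int n = 0; n < N; ++n) {
    arma::cube X(const_cast<double*>(x.begin()) + n * xs, H, W, C, false, true);
    arma::cube Y(out.begin() + n * ys, Ho, Wo, Cout, false, true);
    arma::mat Xm(H * W, C);
    for (int c = 0; c < C; ++c) Xm.col(c) = arma::vectorise(X.slice(c));
    for (int dy = 0; dy < k; ++dy) {
      for (int dxk = 0; dxk < k; ++dxk) {
        arma::mat Ym = Xm * weight_slice(w, k, C, Cout, dy, dxk);
        for (int o = 0; o < Cout; ++o) {
          arma::mat Yr = arma::reshape(Ym.col(o), H, W);
          for (int ww = 0; ww < W; ++ww)
            for (int hh = 0; hh < H; ++hh)
              Y(hh * stride + dy, ww * stride + dxk, o) = Yr(hh, ww) + b[o];
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
List cpp_convT_bwd(NumericVector x, NumericVector w, NumericVector gy,
                   int stride) {
  IntegerVector dx_ = dims_of(x), dw_ = dims_of(w);
  int H = dx_[0], W = dx_[1], C = dx_[2], N = dx_[3];
  int k = dw_[0], Cout = dw_[3];
  int Ho = H * stride, Wo = W * stride;
  NumericVector gx(dim4(H, W, C, N));
  NumericVector gw(dim4(k, k, C, Cout));
  NumericVector gb(Cout);
  size_t xs = (size_t)H * W * C, ys = (size_t)Ho * Wo * Cout;
  arma::cube GW(gw.begin(), (size_t)k * k, C, Cout, false, true);
  for (int n = 0; n < N; ++n) {
    arma::cube X(const_cast<double*>(x.begin()) + n * xs, H, W, C, false, true);
    arma::cube GX(gx.begin() + n * xs, H, W, C, false, true);
    arma::cube GY(const_cast<double*>(gy.begin()) + n * ys, Ho, Wo, Cout, false,
                  true);
    arma::mat Xm(H * W, C);
    for (int c = 0; c < C; ++c) Xm.col(c) = arma::vectorise(X.slice(c));
    for (int dy = 0; dy < k; ++dy) {
      for (int dxk = 0; dxk < k; ++dxk) {
        arma::mat Gm(H * W, Cout);
        for (int o = 0; o < Cout; ++o) {
          arma::mat Gr(H, W);
          for (int ww = 0; ww < W; ++ww)
            for (int hh = 0; hh < H; ++hh)
              Gr(hh, ww) = GY(hh * stride + dy, ww * stride + dxk, o);
          Gm.col(o) = arma::vectorise(Gr);
          if (dy == 0 && dxk == 0) {} // bias handled below once per o
        }
        arma::mat dWm = Xm.t() * Gm;
        for (int o = 0; o < Cout; ++o)
          for (int c = 0; c < C; ++c)
            GW(dy + k * dxk, c, o) += dWm(c, o);
        arma::mat dXm = Gm * weight_slice(w, k, C, Cout, dy, dxk).t();
        for (int c = 0; c < C; ++c) {
          arma::mat acc = arma::reshape(dXm.col(c), H, W);
          GX.slice(c) += acc;
        }
      }
    }
    for (int o = 0; o < Cout; ++o) gb[o] += arma::accu(GY.slice(o));
  }
  return List::create(Named("gx") = gx, Named("gw") = gw, Named("gb") = gb);
}

// [[Rcpp::export]]
List cpp_maxpool_fwd(NumericVector x, int k) {
  IntegerVector dx_ = dims_of(x);
  int H = dx_[0], W = dx_[1], C = dx_[2], N = dx_[3];
  if (H % k || W % k) stop("cpp_maxpool_fwd: H and W must be divisible by k");
  int Ho = H / k, Wo = W / k;
  NumericVector out(dim4(Ho, Wo, C, N));
  IntegerVector arg(dim4(Ho, Wo, C, N)); // 0-based linear index into x
  size_t xs = (size_t)H * W * C, ys = (size_t)Ho * Wo * C;
  for (int n = 0; n < N; ++n) {
    const double* X = x.begin() + n * xs;
    double* Y = out.begin() + n * ys;
    int* A = arg.begin() + n * ys;
    for (int c = 0; c < C; ++c) {
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          double best = -std::numeric_limits<double>::infinity();
          size_t bestix = 0;
          for (int dxk = 0; dxk < k; ++dxk) {
            for (int dy = 0; dy < k; ++dy) {
              size_t ix = (size_t)(ho * k + dy) +
                          (size_t)H * ((wo * k + dxk) + (size_t)W * c);
              if (X[ix] > best) { best = X[ix]; bestix = ix; }
            }
          }
          size_t oix = (size_t)ho + (size_t)Ho * (wo + (size_t)Wo * c);
          Y[oix] = best;
          A[oix] = (int)(bestix + n * xs);
        }
      }
    }
  }
  return List::create(Named("value") = out, Named("argmax") = arg);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(IntegerVector arg, NumericVector gy,
                              IntegerVector xdim) {
  NumericVector gx(dim4(xdim[0], xdim[1], xdim[2], xdim[3]));
  int m = gy.size();
  for (int i = 0; i < m; ++i) gx[arg[i]] += gy[i];
  return gx;
}
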