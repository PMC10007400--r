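// Dense-linear-algebra kernels for the CNN: 'same' 2D cross-correlation
// (im2col + GEMM), 2x2/stride-2 max pooling with argmax bookkeeping, and a
// direct-form-II-transposed IIR filter used by the zero-phase band-pass.
// Layouts follow R column-major arrays: x is (H, W, C, N), kernels are
// (kh, kw, Cin, Cout).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// im2col for one image: out is (H*W) x (kh*kw*Cin), zero padding, stride 1.
static void im2col_same(const double* x, int H, int W, int C,
                        int kh, int kw, arma::mat& col) {
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  for (int c = 0; c < C; ++c) {
    const double* plane = x + (std::size_t)H * W * c;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        double* dst = col.colptr(ki + kh * (kj + kw * c));
        for (int w = 0; w < W; ++w) {
          int src_w = w + kj - pw;
          if (src_w < 0 || src_w >= W) {
            std::memset(dst + (std::size_t)H * w, 0, sizeof(double) * H);
            continue;
          }
          const double* src_col = plane + (std::size_t)H * src_w;
          double* d = dst + (std::size_t)H * w;
          int h0 = std::max(0, ph - ki);        // first valid out row
          int h1 = std::min(H, H + ph - ki);    // one past last valid
          if (h0 > 0) std::memset(d, 0, sizeof(double) * h0);
          if (h1 < H) std::memset(d + h1, 0, sizeof(double) * (H - h1));
          for (int h = h0; h < h1; ++h) d[h] = src_col[h + ki - ph];
        }
      }
    }
  }
}

// col2im accumulation: inverse scatter of im2col_same.
static void col2im_same(const arma::mat& col, int H, int W, int C,
                        int kh, int kw, double* dx) {
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  for (int c = 0; c < C; ++c) {
    double* plane = dx + (std::size_t)H * W * c;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const double* src = col.colptr(ki + kh * (kj + kw * c));
        for (int w = 0; w < W; ++w) {
          int src_w = w + kj - pw;
          if (src_w < 0 || src_w >= W) continue;
          double* d = plane + (std::size_t)H * src_w;
          const double* s = src + (std::size_t)H * w;
          int h0 = std::max(0, ph - ki);
          int h1 = std::min(H, H + ph - ki);
          for (int h = h0; h < h1; ++h) d[h + ki - ph] += s[h];
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_forward(NumericVector x, NumericVector w,
                                 NumericVector b) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cout = wd[3];
  if (wd[2] != C) stop("kernel input channels (%d) != input channels (%d)", (int)wd[2], C);
  if (kh % 2 == 0 || kw % 2 == 0) stop("kernel dims must be odd for same padding");
  NumericVector y((R_xlen_t)H * W * Cout * N);
  y.attr("dim") = IntegerVector::create(H, W, Cout, N);
  arma::mat wm(const_cast<double*>(w.begin()), (std::size_t)kh * kw * C, Cout, false, true);
  arma::mat col((std::size_t)H * W, (std::size_t)kh * kw * C);
  for (int n = 0; n < N; ++n) {
    im2col_same(x.begin() + (std::size_t)H * W * C * n, H, W, C, kh, kw, col);
    arma::mat ym(y.begin() + (std::size_t)H * W * Cout * n, (std::size_t)H * W, Cout, false, true);
    ym = col * wm;
    for (int co = 0; co < Cout; ++co) ym.col(co) += b[co];
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_backward(NumericVector x, NumericVector w, NumericVector dy) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cout = wd[3];
  NumericVector dx((R_xlen_t)H * W * C * N);
  dx.attr("dim") = xd;
  NumericVector dw((R_xlen_t)kh * kw * C * Cout);
  dw.attr("dim") = wd;
  NumericVector db(Cout);
  arma::mat wm(const_cast<double*>(w.begin()), (std::size_t)kh * kw * C, Cout, false, true);
  arma::mat dwm(dw.begin(), (std::size_t)kh * kw * C, Cout, false, true);
  arma::mat col((std::size_t)H * W, (std::size_t)kh * kw * C);
  arma::mat dcol((std::size_t)H * W, (std::size_t)kh * kw * C);
  for (int n = 0; n < N; ++n) {
    arma::mat dym(const_cast<double*>(dy.begin()) + (std::size_t)H * W * Cout * n,
                  (std::size_t)H * W, Cout, false, true);
    im2col_same(x.begin() + (std::size_t)H * W * C * n, H, W, C, kh, kw, col);
    dwm += col.t() * dym;
    for (int co = 0; co < Cout; ++co) db[co] += arma::accu(dym.col(co));
    dcol = dym * wm.t();
    col2im_same(dcol, H, W, C, kh, kw, dx.begin() + (std::size_t)H * W * C * n);
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// [[Rcpp::export]]
List cpp_maxpool_forward(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  if (H % 2 || W % 2) stop("max-pool requires even spatial dims, got %d x %d", H, W);
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((R_xlen_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector arg((R_xlen_t)Ho * Wo * C * N);  // 0-based linear index into x
  R_xlen_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const std::size_t base = (std::size_t)H * W * (c + (std::size_t)C * n);
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho, ++o) {
          std::size_t i00 = base + 2 * ho + (std::size_t)H * (2 * wo);
          std::size_t idx[4] = {i00, i00 + 1, i00 + H, i00 + H + 1};
          double best = x[idx[0]]; std::size_t bi = idx[0];
          for (int k = 1; k < 4; ++k)
            if (x[idx[k]] > best) { best = x[idx[k]]; bi = idx[k]; }
          y[o] = best; arg[o] = (int)bi;
        }
    }
  return List::create(_["y"] = y, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_backward(NumericVector dy, IntegerVector argmax,
                                   IntegerVector xdim) {
  NumericVector dx((R_xlen_t)xdim[0] * xdim[1] * xdim[2] * xdim[3]);
  dx.attr("dim") = xdim;
  for (R_xlen_t i = 0; i < dy.size(); ++i) dx[argmax[i]] += dy[i];
  return dx;
}

// Direct-form-II-transposed IIR filter, a[0] assumed 1 after normalization.
// zi (length max(na,nb)-1, or empty for zeros) sets the initial filter state,
// enabling steady-state start-up as in zero-phase filtering.
// [[Rcpp::export]]
NumericVector cpp_iir_filter(NumericVector b, NumericVector a, NumericVector x,
                             NumericVector zi) {
  const int nb = b.size(), na = a.size(), nf = std::max(na, nb);
  std::vector<double> bb(nf, 0.0), aa(nf, 0.0);
  for (int i = 0; i < nb; ++i) bb[i] = b[i] / a[0];
  for (int i = 0; i < na; ++i) aa[i] = a[i] / a[0];
  std::vector<double> z(nf - 1, 0.0);
  if (zi.size() == (R_xlen_t)(nf - 1))
    for (int i = 0; i < nf - 1; ++i) z[i] = zi[i];
  NumericVector y(x.size());
  for (R_xlen_t n = 0; n < x.size(); ++n) {
    double xn = x[n];
    double yn = bb[0] * xn + z[0];
    for (int i = 1; i < nf - 1; ++i)
      z[i - 1] = bb[i] * xn + z[i] - aa[i] * yn;
    z[nf - 2] = bb[nf - 1] * xn - aa[nf - 1] * yn;
    y[n] = yn;
  }
  return y;
}

// ---- fused batch-norm helpers ----------------------------------------------
// x: (H, W, C, N). Stats are per channel over (H, W, N).

// [[Rcpp::export]]
List cpp_channel_stats(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const std::size_t HW = (std::size_t)xd[0] * xd[1];
  const int C = xd[2], N = xd[3];
  NumericVector mean(C), var(C);
  for (int c = 0; c < C; ++c) {
    double s1 = 0.0, s2 = 0.0;
    for (int n = 0; n < N; ++n) {
      const double* p = x.begin() + HW * (c + (std::size_t)C * n);
      for (std::size_t i = 0; i < HW; ++i) { s1 += p[i]; s2 += p[i] * p[i]; }
    }
    const double m = s1 / (HW * N);
    mean[c] = m;
    var[c] = std::max(s2 / (HW * N) - m * m, 0.0);
  }
  return List::create(_["mean"] = mean, _["var"] = var);
}

// [[Rcpp::export]]
List cpp_bn_forward(NumericVector x, NumericVector mean, NumericVector var,
                    NumericVector gamma, NumericVector beta, double eps) {
  IntegerVector xd = x.attr("dim");
  const std::size_t HW = (std::size_t)xd[0] * xd[1];
  const int C = xd[2], N = xd[3];
  NumericVector y(x.size()), xhat(x.size()), invstd(C);
  y.attr("dim") = xd; xhat.attr("dim") = xd;
  for (int c = 0; c < C; ++c) invstd[c] = 1.0 / std::sqrt(var[c] + eps);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const std::size_t off = HW * (c + (std::size_t)C * n);
      const double m = mean[c], is = invstd[c], g = gamma[c], b = beta[c];
      const double* px = x.begin() + off;
      double* ph = xhat.begin() + off;
      double* py = y.begin() + off;
      for (std::size_t i = 0; i < HW; ++i) {
        const double h = (px[i] - m) * is;
        ph[i] = h; py[i] = h * g + b;
      }
    }
  return List::create(_["y"] = y, _["xhat"] = xhat, _["invstd"] = invstd);
}

// Batch-statistics BN backward; if relu_src is non-empty, the input gradient
// is additionally masked by relu_src > 0 (fused ReLU backward).
// [[Rcpp::export]]
List cpp_bn_backward(NumericVector dy, NumericVector xhat,
                     NumericVector invstd, NumericVector gamma,
                     NumericVector relu_src) {
  IntegerVector xd = dy.attr("dim");
  const std::size_t HW = (std::size_t)xd[0] * xd[1];
  const int C = xd[2], N = xd[3];
  const double mtot = (double)HW * N;
  const bool mask = relu_src.size() == dy.size();
  NumericVector dx(dy.size()), dgamma(C), dbeta(C);
  dx.attr("dim") = xd;
  std::vector<double> s1(C, 0.0), s2(C, 0.0);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const std::size_t off = HW * (c + (std::size_t)C * n);
      const double* pd = dy.begin() + off;
      const double* ph = xhat.begin() + off;
      double a = 0.0, b = 0.0;
      for (std::size_t i = 0; i < HW; ++i) { a += pd[i]; b += pd[i] * ph[i]; }
      s1[c] += a; s2[c] += b;
    }
  for (int c = 0; c < C; ++c) { dgamma[c] = s2[c]; dbeta[c] = s1[c]; }
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const std::size_t off = HW * (c + (std::size_t)C * n);
      const double g = gamma[c], is = invstd[c];
      const double m1 = s1[c] / mtot, m2 = s2[c] / mtot;
      const double* pd = dy.begin() + off;
      const double* ph = xhat.begin() + off;
      const double* pr = mask ? relu_src.begin() + off : nullptr;
      double* px = dx.begin() + off;
      for (std::size_t i = 0; i < HW; ++i) {
        double v = g * (pd[i] - m1 - ph[i] * m2) * is;
        px[i] = (mask && pr[i] <= 0.0) ? 0.0 : v;
      }
    }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}
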