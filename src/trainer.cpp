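// Fused float32 training/inference engine for the attention CNN.
//
// The R code in atcnn.R implements the reference double-precision forward and
// backward passes (validated against finite differences); this file is a
// performance port of the same computation: one C++ call runs an entire
// forward + backward + Adam step on a mini-batch with preallocated buffers,
// single-precision GEMMs and no intermediate R allocations. Layouts match the
// R side exactly: feature maps are column-major (H, W, C, N); conv kernels
// (kh, kw, Cin, Cout) flatten to (kh*kw*Cin) x Cout matrices, the im2col
// layout. Dropout consumes R's RNG stream so training stays reproducible
// under set.seed().
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::fmat;
using arma::fvec;

static void im2col_same_f(const float* x, int H, int W, int C,
                          int kh, int kw, fmat& col) {
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  for (int c = 0; c < C; ++c) {
    const float* plane = x + (std::size_t)H * W * c;
    for (int kj = 0; kj < kw; ++kj)
      for (int ki = 0; ki < kh; ++ki) {
        float* dst = col.colptr(ki + kh * (kj + kw * c));
        for (int w = 0; w < W; ++w) {
          int src_w = w + kj - pw;
          float* d = dst + (std::size_t)H * w;
          if (src_w < 0 || src_w >= W) {
            std::memset(d, 0, sizeof(float) * H);
            continue;
          }
          const float* s = plane + (std::size_t)H * src_w;
          int h0 = std::max(0, ph - ki), h1 = std::min(H, H + ph - ki);
          if (h0 > 0) std::memset(d, 0, sizeof(float) * h0);
          if (h1 < H) std::memset(d + h1, 0, sizeof(float) * (H - h1));
          for (int h = h0; h < h1; ++h) d[h] = s[h + ki - ph];
        }
      }
  }
}

static void col2im_same_f(const fmat& col, int H, int W, int C,
                          int kh, int kw, float* dx) {
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  for (int c = 0; c < C; ++c) {
    float* plane = dx + (std::size_t)H * W * c;
    for (int kj = 0; kj < kw; ++kj)
      for (int ki = 0; ki < kh; ++ki) {
        const float* src = col.colptr(ki + kh * (kj + kw * c));
        for (int w = 0; w < W; ++w) {
          int src_w = w + kj - pw;
          if (src_w < 0 || src_w >= W) continue;
          float* d = plane + (std::size_t)H * src_w;
          const float* s = src + (std::size_t)H * w;
          int h0 = std::max(0, ph - ki), h1 = std::min(H, H + ph - ki);
          for (int h = h0; h < h1; ++h) d[h + ki - ph] += s[h];
        }
      }
  }
}

struct AdamSlot {
  fmat m, v;
  void init(std::size_t r, std::size_t c) {
    m.zeros(r, c); v.zeros(r, c);
  }
};

struct Param {
  fmat w;      // value (vectors stored as n x 1)
  AdamSlot a;
  void init(std::size_t r, std::size_t c) { w.zeros(r, c); a.init(r, c); }
};

struct ConvMod {
  int H, Cin, Cout;                 // input spatial side and channel counts
  Param W, b, g, be;                // kernel, bias, BN gamma/beta
  fvec rmean, rvar;                 // running BN statistics
  fvec bmean, bvar, invstd;         // batch statistics (scratch)
  std::vector<float> z;             // conv+ReLU output (H*H*Cout*maxB)
  std::vector<float> pooled;        // (H/2)^2*Cout*maxB
  std::vector<int> argmax;
};

struct Trainer {
  int input, nmod, r, maxB;
  float dropout, eps_bn;
  long step_count = 0;
  std::vector<int> fcs;             // fc layer sizes incl. flatten and 2
  std::vector<ConvMod> mods;
  Param M0, M1, w7, b7;
  std::vector<Param> fW, fb;
  // scratch
  std::vector<float> xin, ybuf, gbuf1, gbuf2, colbuf, dcolbuf;
  // cbam cache
  fmat Vavg, Vmax, Havg, Hmax, Mc, S;          // C x B / HW x B
  std::vector<int> amax, smax;
  std::vector<float> Fc, P, Fs;
  // fc cache
  fmat X0v, A1d, A2d, D1, D2, probs;
  int side() const { return input >> nmod; }
  int C() const { return mods.back().Cout; }
};

// [[Rcpp::export]]
SEXP cpp_trainer_create(List params, List spec, int max_batch) {
  Trainer* tr = new Trainer();
  tr->input = as<int>(spec["input_size"]);
  IntegerVector filters = spec["filters"];
  tr->nmod = filters.size();
  tr->r = as<int>(spec["r"]);
  tr->dropout = as<double>(spec["dropout"]);
  tr->eps_bn = as<double>(spec["eps_bn"]);
  tr->maxB = max_batch;
  int H = tr->input, Cin = 1;
  std::size_t maxcol = 0, maxz = 0;
  for (int m = 0; m < tr->nmod; ++m) {
    ConvMod cm;
    cm.H = H; cm.Cin = Cin; cm.Cout = filters[m];
    cm.W.init(9 * Cin, cm.Cout);
    cm.b.init(cm.Cout, 1); cm.g.init(cm.Cout, 1); cm.be.init(cm.Cout, 1);
    cm.rmean.zeros(cm.Cout); cm.rvar.ones(cm.Cout);
    cm.bmean.zeros(cm.Cout); cm.bvar.zeros(cm.Cout); cm.invstd.zeros(cm.Cout);
    cm.z.resize((std::size_t)H * H * cm.Cout * max_batch);
    cm.pooled.resize((std::size_t)(H / 2) * (H / 2) * cm.Cout * max_batch);
    cm.argmax.resize(cm.pooled.size());
    maxcol = std::max(maxcol, (std::size_t)H * H * 9 * Cin);
    maxz = std::max(maxz, cm.z.size());
    tr->mods.push_back(std::move(cm));
    H /= 2; Cin = filters[m];
  }
  const int C = Cin, hid = C / tr->r, side = H, HW = side * side;
  tr->M0.init(hid, C); tr->M1.init(C, hid);
  tr->w7.init(49 * 2, 1); tr->b7.init(1, 1);
  const int flat = HW * C;
  IntegerVector fc = spec["fc"];
  tr->fcs = {flat};
  for (int j = 0; j < fc.size(); ++j) tr->fcs.push_back(fc[j]);
  tr->fcs.push_back(2);
  for (std::size_t j = 0; j + 1 < tr->fcs.size(); ++j) {
    Param W, b;
    W.init(tr->fcs[j + 1], tr->fcs[j]);
    b.init(tr->fcs[j + 1], 1);
    tr->fW.push_back(std::move(W)); tr->fb.push_back(std::move(b));
  }
  tr->xin.resize((std::size_t)tr->input * tr->input * max_batch);
  tr->ybuf.resize(maxz); tr->gbuf1.resize(maxz); tr->gbuf2.resize(maxz);
  tr->colbuf.resize(maxcol); tr->dcolbuf.resize(maxcol);
  maxcol = std::max(maxcol, (std::size_t)HW * 98);  // cbam 7x7 conv im2col
  tr->colbuf.resize(maxcol); tr->dcolbuf.resize(maxcol);
  tr->Vavg.zeros(C, max_batch); tr->Vmax.zeros(C, max_batch);
  tr->Havg.zeros(hid, max_batch); tr->Hmax.zeros(hid, max_batch);
  tr->Mc.zeros(C, max_batch); tr->S.zeros(HW, max_batch);
  tr->amax.resize((std::size_t)C * max_batch);
  tr->smax.resize((std::size_t)HW * max_batch);
  tr->Fc.resize((std::size_t)HW * C * max_batch);
  tr->P.resize((std::size_t)HW * 2 * max_batch);
  tr->Fs.resize((std::size_t)HW * C * max_batch);
  tr->A1d.zeros(tr->fcs[1], max_batch); tr->A2d.zeros(tr->fcs[2], max_batch);
  tr->D1.zeros(tr->fcs[1], max_batch); tr->D2.zeros(tr->fcs[2], max_batch);
  tr->probs.zeros(2, max_batch);
  // load initial weights
  auto getm = [&](const char* nm) {
    NumericVector v = params[nm];
    return v;
  };
  for (int m = 0; m < tr->nmod; ++m) {
    char buf[8];
    snprintf(buf, 8, "cw%d", m + 1);
    NumericVector w = getm(buf);
    std::copy(w.begin(), w.end(), tr->mods[m].W.w.begin());
    snprintf(buf, 8, "cb%d", m + 1);
    NumericVector b = getm(buf);
    std::copy(b.begin(), b.end(), tr->mods[m].b.w.begin());
    snprintf(buf, 8, "g%d", m + 1);
    NumericVector g = getm(buf);
    std::copy(g.begin(), g.end(), tr->mods[m].g.w.begin());
    snprintf(buf, 8, "be%d", m + 1);
    NumericVector be = getm(buf);
    std::copy(be.begin(), be.end(), tr->mods[m].be.w.begin());
  }
  {
    NumericVector v = params["M0"];
    std::copy(v.begin(), v.end(), tr->M0.w.begin());
    NumericVector v1 = params["M1"];
    std::copy(v1.begin(), v1.end(), tr->M1.w.begin());
    NumericVector v7 = params["w7"];
    std::copy(v7.begin(), v7.end(), tr->w7.w.begin());
    tr->b7.w(0, 0) = as<double>(params["b7"]);
  }
  for (std::size_t j = 0; j < tr->fW.size(); ++j) {
    char buf[8];
    snprintf(buf, 8, "fW%d", (int)j + 1);
    NumericVector w = params[buf];
    std::copy(w.begin(), w.end(), tr->fW[j].w.begin());
    snprintf(buf, 8, "fb%d", (int)j + 1);
    NumericVector b = params[buf];
    std::copy(b.begin(), b.end(), tr->fb[j].w.begin());
  }
  XPtr<Trainer> ptr(tr, true);
  return ptr;
}

// forward through conv stack + CBAM + FC; fills caches; training toggles
// batch statistics and dropout. x: (H, W, N) doubles in [0, 1].
static void forward_pass(Trainer* tr, NumericVector x, int B, bool training) {
  const std::size_t npx = (std::size_t)tr->input * tr->input;
  for (std::size_t i = 0; i < npx * B; ++i) tr->xin[i] = (float)x[i];
  float* a = tr->xin.data();
  for (int m = 0; m < tr->nmod; ++m) {
    ConvMod& cm = tr->mods[m];
    const int H = cm.H, HW = H * H, Cout = cm.Cout, Cin = cm.Cin;
    fmat col(tr->colbuf.data(), HW, 9 * Cin, false, true);
    for (int n = 0; n < B; ++n) {
      im2col_same_f(a + (std::size_t)HW * Cin * n, H, H, Cin, 3, 3, col);
      fmat zm(cm.z.data() + (std::size_t)HW * Cout * n, HW, Cout, false, true);
      zm = col * cm.W.w;
      for (int c = 0; c < Cout; ++c) {
        float* p = zm.colptr(c);
        const float bb = cm.b.w(c, 0);
        for (int i = 0; i < HW; ++i) p[i] = std::max(p[i] + bb, 0.0f);
      }
    }
    // batch-norm statistics
    const double mtot = (double)HW * B;
    if (training) {
      for (int c = 0; c < Cout; ++c) {
        double s1 = 0, s2 = 0;
        for (int n = 0; n < B; ++n) {
          const float* p = cm.z.data() + HW * ((std::size_t)c + (std::size_t)Cout * n);
          for (int i = 0; i < HW; ++i) { s1 += p[i]; s2 += (double)p[i] * p[i]; }
        }
        const double mu = s1 / mtot;
        cm.bmean(c) = mu;
        cm.bvar(c) = std::max(s2 / mtot - mu * mu, 0.0);
        cm.invstd(c) = 1.0 / std::sqrt(cm.bvar(c) + tr->eps_bn);
      }
    } else {
      // debias the running averages (initialized at mean 0, var 1)
      const double t = (double)tr->step_count;
      const double corr = (t > 0) ? 1.0 - std::pow(0.9, t) : 1.0;
      const double sub = (t > 0) ? std::pow(0.9, t) : 0.0;
      for (int c = 0; c < Cout; ++c) {
        cm.bmean(c) = cm.rmean(c) / corr;
        cm.bvar(c) = std::max(((double)cm.rvar(c) - sub) / corr, 0.0);
        cm.invstd(c) = 1.0 / std::sqrt(cm.bvar(c) + tr->eps_bn);
      }
    }
    // BN + 2x2 max pool fused
    const int Ho = H / 2, HWo = Ho * Ho;
    for (int n = 0; n < B; ++n)
      for (int c = 0; c < Cout; ++c) {
        const std::size_t ozoff = (std::size_t)HW * (c + (std::size_t)Cout * n);
        const std::size_t opoff = (std::size_t)HWo * (c + (std::size_t)Cout * n);
        const float* z = cm.z.data() + ozoff;
        float* po = cm.pooled.data() + opoff;
        int* am = cm.argmax.data() + opoff;
        const float mu = cm.bmean(c), is = cm.invstd(c);
        const float gg = cm.g.w(c, 0), bb = cm.be.w(c, 0);
        for (int wo = 0; wo < Ho; ++wo)
          for (int ho = 0; ho < Ho; ++ho) {
            const int i00 = 2 * ho + H * (2 * wo);
            const int idx[4] = {i00, i00 + 1, i00 + H, i00 + H + 1};
            float best = -1e30f; int bi = idx[0];
            for (int k = 0; k < 4; ++k) {
              const float v = (z[idx[k]] - mu) * is * gg + bb;
              if (v > best) { best = v; bi = idx[k]; }
            }
            po[ho + Ho * wo] = best;
            am[ho + Ho * wo] = bi;
          }
      }
    a = cm.pooled.data();
  }
  // ---- CBAM ----
  const int C = tr->C(), hid = C / tr->r, side = tr->side(), HW = side * side;
  for (int n = 0; n < B; ++n)
    for (int c = 0; c < C; ++c) {
      const float* p = a + HW * ((std::size_t)c + (std::size_t)C * n);
      double s = 0; float mx = p[0]; int mi = 0;
      for (int i = 0; i < HW; ++i) {
        s += p[i];
        if (p[i] > mx) { mx = p[i]; mi = i; }
      }
      tr->Vavg(c, n) = s / HW; tr->Vmax(c, n) = mx;
      tr->amax[(std::size_t)c + (std::size_t)C * n] = mi;
    }
  fmat Vavg = tr->Vavg.cols(0, B - 1), Vmax = tr->Vmax.cols(0, B - 1);
  tr->Havg.cols(0, B - 1) = arma::clamp(tr->M0.w * Vavg, 0.0f, 1e30f);
  tr->Hmax.cols(0, B - 1) = arma::clamp(tr->M0.w * Vmax, 0.0f, 1e30f);
  tr->Mc.cols(0, B - 1) = 1.0f / (1.0f + arma::exp(-(tr->M1.w * tr->Havg.cols(0, B - 1) + tr->M1.w * tr->Hmax.cols(0, B - 1))));
  for (int n = 0; n < B; ++n)
    for (int c = 0; c < C; ++c) {
      const std::size_t off = HW * ((std::size_t)c + (std::size_t)C * n);
      const float w = tr->Mc(c, n);
      const float* p = a + off;
      float* fc = tr->Fc.data() + off;
      for (int i = 0; i < HW; ++i) fc[i] = p[i] * w;
    }
  // spatial planes: channel mean and max of Fc
  for (int n = 0; n < B; ++n) {
    float* pavg = tr->P.data() + (std::size_t)HW * 2 * n;
    float* pmax = pavg + HW;
    int* sm = tr->smax.data() + (std::size_t)HW * n;
    for (int i = 0; i < HW; ++i) { pavg[i] = 0; pmax[i] = -1e30f; }
    for (int c = 0; c < C; ++c) {
      const float* fc = tr->Fc.data() + HW * ((std::size_t)c + (std::size_t)C * n);
      for (int i = 0; i < HW; ++i) {
        pavg[i] += fc[i];
        if (fc[i] > pmax[i]) { pmax[i] = fc[i]; sm[i] = c; }
      }
    }
    for (int i = 0; i < HW; ++i) pavg[i] /= C;
  }
  fmat col7(tr->colbuf.data(), HW, 98, false, true);
  for (int n = 0; n < B; ++n) {
    im2col_same_f(tr->P.data() + (std::size_t)HW * 2 * n, side, side, 2, 7, 7,
                  col7);
    fvec zn = col7 * tr->w7.w + tr->b7.w(0, 0);
    for (int i = 0; i < HW; ++i) tr->S(i, n) = 1.0f / (1.0f + std::exp(-zn(i)));
  }
  for (int n = 0; n < B; ++n)
    for (int c = 0; c < C; ++c) {
      const std::size_t off = HW * ((std::size_t)c + (std::size_t)C * n);
      const float* fc = tr->Fc.data() + off;
      const float* s = tr->S.colptr(n);
      float* fs = tr->Fs.data() + off;
      for (int i = 0; i < HW; ++i) fs[i] = fc[i] * s[i];
    }
  // ---- fully connected ----
  fmat X0(tr->Fs.data(), tr->fcs[0], B, false, true);
  fmat A1 = tr->fW[0].w * X0;
  A1.each_col() += tr->fb[0].w.col(0);
  A1 = arma::clamp(A1, 0.0f, 1e30f);
  if (training && tr->dropout > 0) {
    const float keep = 1.0f - tr->dropout;
    for (arma::uword i = 0; i < A1.n_elem; ++i)
      tr->D1(i % A1.n_rows, i / A1.n_rows) =
        (R::unif_rand() < keep) ? 1.0f / keep : 0.0f;
    A1 %= tr->D1.cols(0, B - 1);
  } else tr->D1.cols(0, B - 1).fill(1.0f);
  tr->A1d.cols(0, B - 1) = A1;
  fmat A2 = tr->fW[1].w * A1;
  A2.each_col() += tr->fb[1].w.col(0);
  A2 = arma::clamp(A2, 0.0f, 1e30f);
  if (training && tr->dropout > 0) {
    const float keep = 1.0f - tr->dropout;
    for (arma::uword i = 0; i < A2.n_elem; ++i)
      tr->D2(i % A2.n_rows, i / A2.n_rows) =
        (R::unif_rand() < keep) ? 1.0f / keep : 0.0f;
    A2 %= tr->D2.cols(0, B - 1);
  } else tr->D2.cols(0, B - 1).fill(1.0f);
  tr->A2d.cols(0, B - 1) = A2;
  fmat Z3 = tr->fW[2].w * A2;
  Z3.each_col() += tr->fb[2].w.col(0);
  for (int n = 0; n < B; ++n) {
    const float mx = std::max(Z3(0, n), Z3(1, n));
    const float e0 = std::exp(Z3(0, n) - mx), e1 = std::exp(Z3(1, n) - mx);
    tr->probs(0, n) = e0 / (e0 + e1);
    tr->probs(1, n) = e1 / (e0 + e1);
  }
}

static void adam_upd(Param& p, const fmat& g, double lr, long t) {
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  const double bc1 = 1.0 - std::pow(b1, (double)t);
  const double bc2 = 1.0 - std::pow(b2, (double)t);
  float* m = p.a.m.memptr();
  float* v = p.a.v.memptr();
  float* w = p.w.memptr();
  const float* gp = g.memptr();
  const std::size_t n = p.w.n_elem;
  for (std::size_t i = 0; i < n; ++i) {
    m[i] = b1 * m[i] + (1.0 - b1) * gp[i];
    v[i] = b2 * v[i] + (1.0 - b2) * gp[i] * gp[i];
    w[i] -= lr * (m[i] / bc1) / (std::sqrt(v[i] / bc2) + eps);
  }
}

// One full training step (forward, backward, Adam, running-stat update).
// Returns the batch loss. y_smooth: smoothed targets, length B.
// [[Rcpp::export]]
double cpp_trainer_step(SEXP ptr_, NumericVector x, NumericVector y_smooth,
                        double lr) {
  XPtr<Trainer> ptr(ptr_);
  Trainer* tr = ptr.get();
  IntegerVector xd = x.attr("dim");
  const int B = xd[2];
  if (B > tr->maxB) stop("batch larger than the trainer's max batch");
  if (B < 2) stop("training step needs a batch of >= 2 (batch norm)");
  forward_pass(tr, x, B, true);
  tr->step_count++;
  const long t = tr->step_count;
  // loss and softmax/BCE gradient
  double loss = 0;
  fmat dZ(2, B);
  for (int n = 0; n < B; ++n) {
    const double pe = std::min(std::max((double)tr->probs(1, n), 1e-7), 1.0 - 1e-7);
    const double y = y_smooth[n];
    loss += -(y * std::log(pe) + (1.0 - y) * std::log(1.0 - pe));
    const double g = -(y / pe - (1.0 - y) / (1.0 - pe)) / B;
    const double d = g * pe * (1.0 - pe);
    dZ(0, n) = -d; dZ(1, n) = d;
  }
  loss /= B;
  // ---- FC backward ----
  fmat A2 = tr->A2d.cols(0, B - 1), A1 = tr->A1d.cols(0, B - 1);
  fmat X0(tr->Fs.data(), tr->fcs[0], B, false, true);
  fmat gW3 = dZ * A2.t();
  fvec gb3 = arma::sum(dZ, 1);
  fmat dA2 = tr->fW[2].w.t() * dZ;
  dA2 %= tr->D2.cols(0, B - 1);
  dA2.elem(arma::find(A2 <= 0)).zeros();
  fmat gW2 = dA2 * A1.t();
  fvec gb2 = arma::sum(dA2, 1);
  fmat dA1 = tr->fW[1].w.t() * dA2;
  dA1 %= tr->D1.cols(0, B - 1);
  dA1.elem(arma::find(A1 <= 0)).zeros();
  fmat gW1 = dA1 * X0.t();
  fvec gb1 = arma::sum(dA1, 1);
  fmat dX0 = tr->fW[0].w.t() * dA1;          // flat x B = dFs
  // ---- CBAM backward ----
  const int C = tr->C(), hid = C / tr->r, side = tr->side(), HW = side * side;
  const float* pool3 = tr->mods.back().pooled.data();
  // dFc = dFs * S (broadcast) ; dS = sum_c dFs * Fc
  std::vector<float>& dFcv = tr->gbuf1;      // HW*C*B floats
  fmat dS(HW, B, arma::fill::zeros);
  for (int n = 0; n < B; ++n) {
    const float* s = tr->S.colptr(n);
    float* ds = dS.colptr(n);
    for (int c = 0; c < C; ++c) {
      const std::size_t off = HW * ((std::size_t)c + (std::size_t)C * n);
      const float* dfs = dX0.memptr() + off;
      const float* fc = tr->Fc.data() + off;
      float* dfc = dFcv.data() + off;
      for (int i = 0; i < HW; ++i) {
        dfc[i] = dfs[i] * s[i];
        ds[i] += dfs[i] * fc[i];
      }
    }
  }
  // through sigmoid and the 7x7 conv
  fmat gw7(98, 1, arma::fill::zeros);
  float gb7 = 0;
  fmat col7(tr->colbuf.data(), HW, 98, false, true);
  fmat dcol7(tr->dcolbuf.data(), HW, 98, false, true);
  std::vector<float> dPn((std::size_t)HW * 2);
  for (int n = 0; n < B; ++n) {
    fvec dz(HW);
    const float* s = tr->S.colptr(n);
    const float* ds = dS.colptr(n);
    for (int i = 0; i < HW; ++i) dz(i) = ds[i] * s[i] * (1.0f - s[i]);
    im2col_same_f(tr->P.data() + (std::size_t)HW * 2 * n, side, side, 2, 7, 7,
                  col7);
    gw7 += col7.t() * dz;
    gb7 += arma::accu(dz);
    dcol7 = dz * tr->w7.w.t();
    std::fill(dPn.begin(), dPn.end(), 0.0f);
    col2im_same_f(dcol7, side, side, 2, 7, 7, dPn.data());
    // scatter into dFc: avg plane /C to all channels, max plane to argmax
    const int* sm = tr->smax.data() + (std::size_t)HW * n;
    for (int c = 0; c < C; ++c) {
      float* dfc = dFcv.data() + HW * ((std::size_t)c + (std::size_t)C * n);
      for (int i = 0; i < HW; ++i) dfc[i] += dPn[i] / C;
    }
    for (int i = 0; i < HW; ++i) {
      float* dfc = dFcv.data() + HW * ((std::size_t)sm[i] + (std::size_t)C * n);
      dfc[i] += dPn[HW + i];
    }
  }
  // channel attention backward
  fmat dMc(C, B);
  std::vector<float>& dxv = tr->gbuf2;       // gradient wrt pooled3
  for (int n = 0; n < B; ++n)
    for (int c = 0; c < C; ++c) {
      const std::size_t off = HW * ((std::size_t)c + (std::size_t)C * n);
      const float* dfc = dFcv.data() + off;
      const float* p = pool3 + off;
      const float w = tr->Mc(c, n);
      float* dx = dxv.data() + off;
      double s = 0;
      for (int i = 0; i < HW; ++i) {
        dx[i] = dfc[i] * w;
        s += (double)dfc[i] * p[i];
      }
      dMc(c, n) = s;
    }
  fmat Mcb = tr->Mc.cols(0, B - 1);
  fmat dA = dMc % Mcb % (1.0f - Mcb);
  fmat Havg = tr->Havg.cols(0, B - 1), Hmax = tr->Hmax.cols(0, B - 1);
  fmat dHavg = tr->M1.w.t() * dA;
  dHavg.elem(arma::find(Havg <= 0)).zeros();
  fmat dHmax = tr->M1.w.t() * dA;
  dHmax.elem(arma::find(Hmax <= 0)).zeros();
  fmat gM1 = dA * (Havg + Hmax).t();
  fmat gM0 = dHavg * tr->Vavg.cols(0, B - 1).t() +
             dHmax * tr->Vmax.cols(0, B - 1).t();
  fmat dVavg = tr->M0.w.t() * dHavg;
  fmat dVmax = tr->M0.w.t() * dHmax;
  for (int n = 0; n < B; ++n)
    for (int c = 0; c < C; ++c) {
      const std::size_t off = HW * ((std::size_t)c + (std::size_t)C * n);
      float* dx = dxv.data() + off;
      const float dva = dVavg(c, n) / HW;
      for (int i = 0; i < HW; ++i) dx[i] += dva;
      dx[tr->amax[(std::size_t)c + (std::size_t)C * n]] += dVmax(c, n);
    }
  // ---- conv modules backward (uses gbuf1/gbuf2 as ping-pong) ----
  float* dpool = dxv.data();                 // grad wrt mods[last].pooled
  std::vector<fmat> gW(tr->nmod);
  std::vector<fvec> gcb(tr->nmod), gg(tr->nmod), gbe(tr->nmod);
  for (int m = tr->nmod - 1; m >= 0; --m) {
    ConvMod& cm = tr->mods[m];
    const int H = cm.H, HWm = H * H, Cout = cm.Cout, Cin = cm.Cin;
    const int Ho = H / 2, HWo = Ho * Ho;
    const double mtot = (double)HWm * B;
    // unpool into ybuf (zero-filled), then BN backward in place
    float* dy = tr->ybuf.data();
    std::memset(dy, 0, sizeof(float) * (std::size_t)HWm * Cout * B);
    for (int n = 0; n < B; ++n)
      for (int c = 0; c < Cout; ++c) {
        const std::size_t ooff = (std::size_t)HWo * (c + (std::size_t)Cout * n);
        const std::size_t zoff = (std::size_t)HWm * (c + (std::size_t)Cout * n);
        const float* dp = dpool + ooff;
        const int* am = cm.argmax.data() + ooff;
        float* d = dy + zoff;
        for (int i = 0; i < HWo; ++i) d[am[i]] += dp[i];
      }
    gg[m].zeros(Cout); gbe[m].zeros(Cout);
    for (int c = 0; c < Cout; ++c) {
      const float mu = cm.bmean(c), is = cm.invstd(c);
      double s1 = 0, s2 = 0;
      for (int n = 0; n < B; ++n) {
        const std::size_t off = (std::size_t)HWm * (c + (std::size_t)Cout * n);
        const float* d = dy + off;
        const float* z = cm.z.data() + off;
        for (int i = 0; i < HWm; ++i) {
          s1 += d[i];
          s2 += (double)d[i] * (z[i] - mu) * is;
        }
      }
      gg[m](c) = s2; gbe[m](c) = s1;
      const float m1 = s1 / mtot, m2 = s2 / mtot;
      const float gs = cm.g.w(c, 0) * is;
      for (int n = 0; n < B; ++n) {
        const std::size_t off = (std::size_t)HWm * (c + (std::size_t)Cout * n);
        float* d = dy + off;
        const float* z = cm.z.data() + off;
        for (int i = 0; i < HWm; ++i) {
          const float xh = (z[i] - mu) * is;
          d[i] = (z[i] > 0) ? gs * (d[i] - m1 - xh * m2) : 0.0f;
        }
      }
    }
    // conv backward
    gW[m].zeros(9 * Cin, Cout); gcb[m].zeros(Cout);
    const float* inp = (m == 0) ? tr->xin.data() : tr->mods[m - 1].pooled.data();
    float* dinp = (dpool == tr->gbuf1.data()) ? tr->gbuf2.data()
                                              : tr->gbuf1.data();
    if (m > 0)
      std::memset(dinp, 0, sizeof(float) * (std::size_t)HWm * Cin * B);
    fmat col(tr->colbuf.data(), HWm, 9 * Cin, false, true);
    fmat dcol(tr->dcolbuf.data(), HWm, 9 * Cin, false, true);
    for (int n = 0; n < B; ++n) {
      fmat dyn(dy + (std::size_t)HWm * Cout * n, HWm, Cout, false, true);
      im2col_same_f(inp + (std::size_t)HWm * Cin * n, H, H, Cin, 3, 3, col);
      gW[m] += col.t() * dyn;
      gcb[m] += arma::sum(dyn, 0).t();
      if (m > 0) {
        dcol = dyn * cm.W.w.t();
        col2im_same_f(dcol, H, H, Cin, 3, 3,
                      dinp + (std::size_t)HWm * Cin * n);
      }
    }
    dpool = dinp;
  }
  // ---- Adam updates ----
  for (int m = 0; m < tr->nmod; ++m) {
    adam_upd(tr->mods[m].W, gW[m], lr, t);
    adam_upd(tr->mods[m].b, fmat(gcb[m]), lr, t);
    adam_upd(tr->mods[m].g, fmat(gg[m]), lr, t);
    adam_upd(tr->mods[m].be, fmat(gbe[m]), lr, t);
    // running statistics (momentum 0.1); frozen when nothing is learned
    if (lr > 0) {
      tr->mods[m].rmean = 0.9f * tr->mods[m].rmean + 0.1f * tr->mods[m].bmean;
      tr->mods[m].rvar = 0.9f * tr->mods[m].rvar + 0.1f * tr->mods[m].bvar;
    }
  }
  adam_upd(tr->M0, gM0, lr, t);
  adam_upd(tr->M1, gM1, lr, t);
  adam_upd(tr->w7, gw7, lr, t);
  adam_upd(tr->b7, fmat(1, 1, arma::fill::value(gb7)), lr, t);
  adam_upd(tr->fW[0], gW1, lr, t); adam_upd(tr->fb[0], fmat(gb1), lr, t);
  adam_upd(tr->fW[1], gW2, lr, t); adam_upd(tr->fb[1], fmat(gb2), lr, t);
  adam_upd(tr->fW[2], gW3, lr, t); adam_upd(tr->fb[2], fmat(gb3), lr, t);
  return loss;
}

// Inference probabilities (running statistics, no dropout).
// [[Rcpp::export]]
NumericVector cpp_trainer_predict(SEXP ptr_, NumericVector x) {
  XPtr<Trainer> ptr(ptr_);
  Trainer* tr = ptr.get();
  IntegerVector xd = x.attr("dim");
  const int B = xd[2];
  if (B > tr->maxB) stop("batch larger than the trainer's max batch");
  forward_pass(tr, x, B, false);
  NumericVector out(B);
  for (int n = 0; n < B; ++n) out[n] = tr->probs(1, n);
  return out;
}

// Extract weights + running stats back to R (doubles, R layouts).
// [[Rcpp::export]]
List cpp_trainer_get_params(SEXP ptr_) {
  XPtr<Trainer> ptr(ptr_);
  Trainer* tr = ptr.get();
  List params, state;
  for (int m = 0; m < tr->nmod; ++m) {
    ConvMod& cm = tr->mods[m];
    char buf[8];
    NumericVector w(cm.W.w.begin(), cm.W.w.end());
    w.attr("dim") = IntegerVector::create(3, 3, cm.Cin, cm.Cout);
    snprintf(buf, 8, "cw%d", m + 1); params[buf] = w;
    snprintf(buf, 8, "cb%d", m + 1);
    params[buf] = NumericVector(cm.b.w.begin(), cm.b.w.end());
    snprintf(buf, 8, "g%d", m + 1);
    params[buf] = NumericVector(cm.g.w.begin(), cm.g.w.end());
    snprintf(buf, 8, "be%d", m + 1);
    params[buf] = NumericVector(cm.be.w.begin(), cm.be.w.end());
    snprintf(buf, 8, "rm%d", m + 1);
    state[buf] = NumericVector(cm.rmean.begin(), cm.rmean.end());
    snprintf(buf, 8, "rv%d", m + 1);
    state[buf] = NumericVector(cm.rvar.begin(), cm.rvar.end());
  }
  state["bn_t"] = (double)tr->step_count;
  {
    NumericVector m0(tr->M0.w.begin(), tr->M0.w.end());
    m0.attr("dim") = IntegerVector::create(tr->M0.w.n_rows, tr->M0.w.n_cols);
    params["M0"] = m0;
    NumericVector m1(tr->M1.w.begin(), tr->M1.w.end());
    m1.attr("dim") = IntegerVector::create(tr->M1.w.n_rows, tr->M1.w.n_cols);
    params["M1"] = m1;
    NumericVector w7(tr->w7.w.begin(), tr->w7.w.end());
    w7.attr("dim") = IntegerVector::create(7, 7, 2, 1);
    params["w7"] = w7;
    params["b7"] = tr->b7.w(0, 0);
  }
  for (std::size_t j = 0; j < tr->fW.size(); ++j) {
    char buf[8];
    NumericVector w(tr->fW[j].w.begin(), tr->fW[j].w.end());
    w.attr("dim") = IntegerVector::create(tr->fW[j].w.n_rows,
                                          tr->fW[j].w.n_cols);
    snprintf(buf, 8, "fW%d", (int)j + 1); params[buf] = w;
    snprintf(buf, 8, "fb%d", (int)j + 1);
    params[buf] = NumericVector(tr->fb[j].w.begin(), tr->fb[j].w.end());
  }
  return List::create(_["params"] = params, _["state"] = state);
}

// Restore weights + running stats (e.g. best-epoch snapshot).
// [[Rcpp::export]]
void cpp_trainer_set_params(SEXP ptr_, List params, List state) {
  XPtr<Trainer> ptr(ptr_);
  Trainer* tr = ptr.get();
  for (int m = 0; m < tr->nmod; ++m) {
    ConvMod& cm = tr->mods[m];
    char buf[8];
    snprintf(buf, 8, "cw%d", m + 1);
    NumericVector w = params[buf];
    std::copy(w.begin(), w.end(), cm.W.w.begin());
    snprintf(buf, 8, "cb%d", m + 1);
    NumericVector b = params[buf];
    std::copy(b.begin(), b.end(), cm.b.w.begin());
    snprintf(buf, 8, "g%d", m + 1);
    NumericVector g = params[buf];
    std::copy(g.begin(), g.end(), cm.g.w.begin());
    snprintf(buf, 8, "be%d", m + 1);
    NumericVector be = params[buf];
    std::copy(be.begin(), be.end(), cm.be.w.begin());
    snprintf(buf, 8, "rm%d", m + 1);
    NumericVector rm = state[buf];
    std::copy(rm.begin(), rm.end(), cm.rmean.begin());
    snprintf(buf, 8, "rv%d", m + 1);
    NumericVector rv = state[buf];
    std::copy(rv.begin(), rv.end(), cm.rvar.begin());
  }
  if (state.containsElementNamed("bn_t"))
    tr->step_count = (long)as<double>(state["bn_t"]);
  NumericVector m0 = params["M0"];
  std::copy(m0.begin(), m0.end(), tr->M0.w.begin());
  NumericVector m1 = params["M1"];
  std::copy(m1.begin(), m1.end(), tr->M1.w.begin());
  NumericVector w7 = params["w7"];
  std::copy(w7.begin(), w7.end(), tr->w7.w.begin());
  tr->b7.w(0, 0) = as<double>(params["b7"]);
  for (std::size_t j = 0; j < tr->fW.size(); ++j) {
    char buf[8];
    snprintf(buf, 8, "fW%d", (int)j + 1);
    NumericVector w = params[buf];
    std::copy(w.begin(), w.end(), tr->fW[j].w.begin());
    snprintf(buf, 8, "fb%d", (int)j + 1);
    NumericVector b = params[buf];
    std::copy(b.begin(), b.end(), tr->fb[j].w.begin());
  }
}
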