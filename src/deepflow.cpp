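// DeepFlow-style convolutional classifier for small two-channel imaging
// flow cytometry images, implemented directly on single-precision GEMM.
//
// Feature maps are stored as fmat F of shape (C, H*W*N): spatial index
// p = i + H*j (column-major within an image), column index p + H*W*n.
// 3x3 convolutions use an im2col matrix K of shape (9*C, H*W*N) with row
// block k*C..k*C+C-1 holding the k-th neighbourhood offset, so each offset
// is a contiguous-column shifted copy of F (fast memcpy construction).
// Weight matrices are (C_out, 9*C_in) matching that row order; 1x1 paths
// multiply F directly. Batch norm keeps running moments for inference.
//
// The architecture (stem conv -> optional pool -> S scales of dual-path
// 1x1/3x3 subunit blocks with concatenation, max pools between scales ->
// global average pool -> fully connected -> softmax) and the training loop
// hyper-parameters are driven from R; this file only knows tensors.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#ifdef __GLIBC__
#include <malloc.h>
// Every training step allocates ~1 GB of short-lived conv workspaces; with
// default malloc tuning glibc mmap/munmaps them, so each batch pays the
// zero-fill page-fault cost again. Keeping large blocks on the heap roughly
// halves the per-batch wall time on one CPU.
static int mnflow_malloc_tuning = []() {
  mallopt(M_MMAP_MAX, 0);
  mallopt(M_TRIM_THRESHOLD, -1);
  return 0;
}();
#endif
using namespace arma;
using Rcpp::List;
using Rcpp::IntegerVector;
using Rcpp::NumericVector;
using Rcpp::NumericMatrix;

static const float BN_EPS = 1e-5f;

struct UnitSpec { int kernel, in_ch, out_ch; };

struct Arch {
  std::vector<UnitSpec> units;     // stem, then per scale/block: 1x1, 3x3
  std::vector<int> blocks;         // blocks per scale
  std::vector<int> widths;         // concatenated width per scale
  int stem_width, n_scales, n_classes, in_channels, img;
  bool stem_pool;
};

static Arch parse_arch(const List& cfg) {
  Arch a;
  a.img = Rcpp::as<int>(cfg["img"]);
  a.in_channels = Rcpp::as<int>(cfg["in_channels"]);
  a.n_classes = Rcpp::as<int>(cfg["n_classes"]);
  a.stem_width = Rcpp::as<int>(cfg["stem_width"]);
  a.stem_pool = Rcpp::as<bool>(cfg["stem_pool"]);
  a.widths = Rcpp::as<std::vector<int>>(cfg["block_widths"]);
  a.blocks = Rcpp::as<std::vector<int>>(cfg["n_blocks_per_scale"]);
  a.n_scales = (int)a.widths.size();
  a.units.push_back({3, a.in_channels, a.stem_width});
  int c_in = a.stem_width;
  for (int s = 0; s < a.n_scales; s++) {
    int half = a.widths[s] / 2;
    for (int b = 0; b < a.blocks[s]; b++) {
      a.units.push_back({1, c_in, half});
      a.units.push_back({3, c_in, half});
      c_in = 2 * half;
    }
  }
  return a;
}

static fmat as_f(SEXP x) { return conv_to<fmat>::from(Rcpp::as<mat>(x)); }
static NumericMatrix as_r(const fmat& x) {
  return Rcpp::wrap(conv_to<mat>::from(x));
}

// ---- im2col / col2im for 3x3 same-padding -------------------------------

static void im2col3(const fmat& F, int H, int W, int N, fmat& K) {
  const int C = F.n_rows, HW = H * W;
  K.zeros(9 * C, (uword)HW * N);
  int k = 0;
  for (int dj = -1; dj <= 1; dj++) {
    for (int di = -1; di <= 1; di++, k++) {
      int ilo = std::max(0, -di), ihi = std::min(H, H - di);  // valid rows
      if (ilo >= ihi) continue;
      for (int n = 0; n < N; n++) {
        for (int j = 0; j < W; j++) {
          int sj = j + dj;
          if (sj < 0 || sj >= W) continue;
          for (int i = ilo; i < ihi; i++) {
            std::memcpy(K.colptr((uword)HW * n + (uword)H * j + i) + (uword)k * C,
                        F.colptr((uword)HW * n + (uword)H * sj + (i + di)),
                        sizeof(float) * C);
          }
        }
      }
    }
  }
}

static void col2im3(const fmat& dK, int H, int W, int N, int C, fmat& dF) {
  const int HW = H * W;
  dF.zeros(C, (uword)HW * N);
  int k = 0;
  for (int dj = -1; dj <= 1; dj++) {
    for (int di = -1; di <= 1; di++, k++) {
      for (int n = 0; n < N; n++) {
        for (int j = 0; j < W; j++) {
          int sj = j + dj;
          if (sj < 0 || sj >= W) continue;
          for (int i = std::max(0, -di); i < std::min(H, H - di); i++) {
            float* dst = dF.colptr((uword)HW * n + (uword)H * sj + (i + di));
            const float* src =
                dK.colptr((uword)HW * n + (uword)H * j + i) + (uword)k * C;
            for (int c = 0; c < C; c++) dst[c] += src[c];
          }
        }
      }
    }
  }
}

// ---- 2x2 max pool --------------------------------------------------------

static void maxpool2(const fmat& F, int H, int W, int N, fmat& P, umat& idx) {
  const int C = F.n_rows, Ho = H / 2, Wo = W / 2, HWo = Ho * Wo, HW = H * W;
  P.set_size(C, (uword)HWo * N);
  idx.set_size(C, (uword)HWo * N);
  for (int n = 0; n < N; n++) {
    for (int jo = 0; jo < Wo; jo++) {
      for (int io = 0; io < Ho; io++) {
        uword q = (uword)HWo * n + (uword)Ho * jo + io;
        uword cand[4] = {
          (uword)HW * n + (uword)H * (2 * jo) + 2 * io,
          (uword)HW * n + (uword)H * (2 * jo) + 2 * io + 1,
          (uword)HW * n + (uword)H * (2 * jo + 1) + 2 * io,
          (uword)HW * n + (uword)H * (2 * jo + 1) + 2 * io + 1};
        for (int c = 0; c < C; c++) {
          float best = F(c, cand[0]); uword bi = cand[0];
          for (int t = 1; t < 4; t++) {
            float v = F(c, cand[t]);
            if (v > best) { best = v; bi = cand[t]; }
          }
          P(c, q) = best; idx(c, q) = bi;
        }
      }
    }
  }
}

static void maxpool2_back(const fmat& dP, const umat& idx, int C, uword ncolF,
                          fmat& dF) {
  dF.zeros(C, ncolF);
  for (uword q = 0; q < dP.n_cols; q++)
    for (int c = 0; c < C; c++) dF(c, idx(c, q)) += dP(c, q);
}

// ---- batch norm ----------------------------------------------------------

struct BNCache { fmat xhat; fvec invstd; };

static void bn_forward_train(fmat& X, const fvec& gamma, const fvec& beta,
                             fvec& rmean, fvec& rvar, BNCache& cache,
                             float momentum = 0.1f) {
  const uword n = X.n_cols;
  fvec m = mean(X, 1), v = var(X, 1, 1);  // biased variance
  cache.invstd = 1.0f / sqrt(v + BN_EPS);
  X.each_col() -= m;
  X.each_col() %= cache.invstd;
  cache.xhat = X;
  X.each_col() %= gamma;
  X.each_col() += beta;
  rmean = (1 - momentum) * rmean + momentum * m;
  float bessel = n > 1 ? (float)n / (n - 1) : 1.0f;
  rvar = (1 - momentum) * rvar + momentum * bessel * v;
}

static void bn_forward_infer(fmat& X, const fvec& gamma, const fvec& beta,
                             const fvec& rmean, const fvec& rvar) {
  fvec invstd = 1.0f / sqrt(rvar + BN_EPS);
  X.each_col() -= rmean;
  X.each_col() %= (invstd % gamma);
  X.each_col() += beta;
}

static void bn_backward(const fmat& dY, const BNCache& cache,
                        const fvec& gamma, fmat& dX, fvec& dgamma,
                        fvec& dbeta) {
  const float n = (float)dY.n_cols;
  dgamma = sum(dY % cache.xhat, 1);
  dbeta = sum(dY, 1);
  dX = dY;
  dX.each_col() %= gamma;          // dxhat
  fvec s1 = sum(dX, 1), s2 = sum(dX % cache.xhat, 1);
  dX *= n;
  dX.each_col() -= s1;
  dX -= cache.xhat.each_col() % s2;
  dX.each_col() %= (cache.invstd / n);
}

// ---- forward/backward through the whole network --------------------------

struct UnitParams { fmat W; fvec gamma, beta; };
struct UnitState { fvec rmean, rvar; };

struct Caches {
  std::vector<fmat> K;        // im2col input (3x3) or conv input (1x1)
  std::vector<BNCache> bn;
  std::vector<fmat> relu_out; // post-relu output (mask source)
  std::vector<umat> pool_idx;
  std::vector<uword> pool_ncol_in;
  std::vector<int> pool_C;
};

static void unpack(const List& params, const List& running, const Arch& a,
                   std::vector<UnitParams>& up, std::vector<UnitState>& us,
                   fmat& fcW, fvec& fcb) {
  const int U = (int)a.units.size();
  up.resize(U); us.resize(U);
  for (int u = 0; u < U; u++) {
    up[u].W = as_f(params[3 * u]);
    up[u].gamma = conv_to<fvec>::from(Rcpp::as<vec>(params[3 * u + 1]));
    up[u].beta = conv_to<fvec>::from(Rcpp::as<vec>(params[3 * u + 2]));
    us[u].rmean = conv_to<fvec>::from(Rcpp::as<vec>(running[2 * u]));
    us[u].rvar = conv_to<fvec>::from(Rcpp::as<vec>(running[2 * u + 1]));
  }
  fcW = as_f(params[3 * U]);
  fcb = conv_to<fvec>::from(Rcpp::as<vec>(params[3 * U + 1]));
}

// Forward pass. In training mode (train = true) channels are normalised by
// batch statistics and running moments are updated with `momentum`
// (momentum 1 = copy, used by the post-training stats pass); inference
// uses the stored running stats. Caches are optional (needed for backward).
// Returns class probabilities (n_classes, N); gap receives pooled features.
static fmat forward(const fmat& X0, const Arch& a,
                    std::vector<UnitParams>& up, std::vector<UnitState>& us,
                    const fmat& fcW, const fvec& fcb, int N, bool train,
                    Caches* cc, fmat& gap, std::vector<int>& dimH,
                    float momentum = 0.1f) {
  int H = a.img;
  fmat F = X0;  // (C_in, H*W*N)
  int u = 0;
  const int U = (int)a.units.size();
  if (cc) {
    cc->K.resize(U); cc->bn.resize(U); cc->relu_out.resize(U);
  }
  dimH.assign(U, 0);

  auto run_unit = [&](const fmat& input, int unit, int curH) -> fmat {
    const UnitSpec& spec = a.units[unit];
    fmat Y;
    if (spec.kernel == 3) {
      fmat K;
      im2col3(input, curH, curH, N, K);
      Y = up[unit].W * K;
      if (cc) cc->K[unit] = std::move(K);
    } else {
      Y = up[unit].W * input;
      if (cc) cc->K[unit] = input;
    }
    if (train) {
      BNCache local;
      bn_forward_train(Y, up[unit].gamma, up[unit].beta, us[unit].rmean,
                       us[unit].rvar, cc ? cc->bn[unit] : local, momentum);
    } else
      bn_forward_infer(Y, up[unit].gamma, up[unit].beta, us[unit].rmean,
                       us[unit].rvar);
    Y.transform([](float v) { return v > 0 ? v : 0.0f; });
    dimH[unit] = curH;
    if (cc) cc->relu_out[unit] = Y;
    return Y;
  };

  auto pool = [&](fmat& F_, int& H_) {
    fmat P; umat idx;
    maxpool2(F_, H_, H_, N, P, idx);
    if (cc) {
      cc->pool_idx.push_back(std::move(idx));
      cc->pool_ncol_in.push_back(F_.n_cols);
      cc->pool_C.push_back((int)F_.n_rows);
    }
    F_ = std::move(P);
    H_ /= 2;
  };

  F = run_unit(F, u++, H);
  if (a.stem_pool) pool(F, H);
  for (int s = 0; s < a.n_scales; s++) {
    for (int b = 0; b < a.blocks[s]; b++) {
      fmat p1 = run_unit(F, u++, H);
      fmat p3 = run_unit(F, u++, H);
      F = join_cols(p1, p3);
    }
    if (s + 1 < a.n_scales) pool(F, H);
  }

  // global average pool -> (C, N)
  const int HW = H * H, C = (int)F.n_rows;
  gap.set_size(C, N);
  for (int n = 0; n < N; n++)
    gap.col(n) = mean(F.cols((uword)HW * n, (uword)HW * (n + 1) - 1), 1);

  fmat logits = fcW * gap;
  logits.each_col() += fcb;
  logits.each_row() -= max(logits, 0);
  fmat P = exp(logits);
  frowvec Z = sum(P, 0);
  P.each_row() /= Z;
  return P;
}

// [[Rcpp::export]]
Rcpp::List cpp_df_step(Rcpp::List params, Rcpp::List running,
                       Rcpp::List adam_m, Rcpp::List adam_v,
                       const arma::mat& Xr, const arma::ivec& y,
                       const arma::vec& class_w, Rcpp::List cfg,
                       double lr, double l2, double beta1, double beta2,
                       double adam_eps, int adam_t) {
  Arch a = parse_arch(cfg);
  const int N = (int)Xr.n_cols, HW = a.img * a.img, Cin = a.in_channels;
  // reshape (HW*C, N) double -> (C, HW*N) float
  fmat X0(Cin, (uword)HW * N);
  for (int n = 0; n < N; n++)
    for (int c = 0; c < Cin; c++)
      for (int p = 0; p < HW; p++)
        X0(c, (uword)HW * n + p) = (float)Xr((uword)HW * c + p, n);

  std::vector<UnitParams> up; std::vector<UnitState> us;
  fmat fcW; fvec fcb;
  unpack(params, running, a, up, us, fcW, fcb);

  Caches cc; fmat gap; std::vector<int> dimH;
  fmat P = forward(X0, a, up, us, fcW, fcb, N, true, &cc, gap, dimH);

  // weighted cross-entropy
  fvec wn(N); double wsum = 0, loss = 0; int correct = 0;
  for (int n = 0; n < N; n++) {
    wn(n) = (float)class_w(y(n)); wsum += wn(n);
    loss += wn(n) * -std::log(std::max(P(y(n), n), 1e-12f));
    if ((int)index_max(P.col(n)) == y(n)) correct++;
  }
  loss /= wsum;

  fmat dlogits = P;
  for (int n = 0; n < N; n++) {
    dlogits(y(n), n) -= 1.0f;
    dlogits.col(n) *= wn(n) / (float)wsum;
  }

  const int U = (int)a.units.size();
  std::vector<fmat> gW(U); std::vector<fvec> gGamma(U), gBeta(U);

  fmat gfcW = dlogits * gap.t();
  fvec gfcb = sum(dlogits, 1);
  fmat dgap = fcW.t() * dlogits;

  // un-pool the global average
  int Hlast = dimH[U - 1];
  int HWl = Hlast * Hlast, Clast = (int)dgap.n_rows;
  fmat dF(Clast, (uword)HWl * N);
  for (int n = 0; n < N; n++)
    dF.cols((uword)HWl * n, (uword)HWl * (n + 1) - 1) =
        repmat(dgap.col(n) / (float)HWl, 1, HWl);

  auto unit_back = [&](fmat& dY, int unit, int curH) -> fmat {
    // through relu
    const fmat& out = cc.relu_out[unit];
    dY %= conv_to<fmat>::from(out > 0);
    fmat dxhat_in; fvec dg, db;
    bn_backward(dY, cc.bn[unit], up[unit].gamma, dxhat_in, dg, db);
    gGamma[unit] = dg; gBeta[unit] = db;
    const UnitSpec& spec = a.units[unit];
    fmat dIn;
    if (spec.kernel == 3) {
      gW[unit] = dxhat_in * cc.K[unit].t();
      fmat dK = up[unit].W.t() * dxhat_in;
      col2im3(dK, curH, curH, N, spec.in_ch, dIn);
    } else {
      gW[unit] = dxhat_in * cc.K[unit].t();
      dIn = up[unit].W.t() * dxhat_in;
    }
    return dIn;
  };

  // walk architecture in reverse
  int u = U - 1;
  int pool_i = (int)cc.pool_idx.size() - 1;
  for (int s = a.n_scales - 1; s >= 0; s--) {
    for (int b = a.blocks[s] - 1; b >= 0; b--) {
      int u3 = u--, u1 = u--;
      int half = a.units[u1].out_ch;
      int curH = dimH[u1];
      fmat d1 = dF.rows(0, half - 1);
      fmat d3 = dF.rows(half, 2 * half - 1);
      fmat dIn = unit_back(d1, u1, curH);
      dIn += unit_back(d3, u3, curH);
      dF = std::move(dIn);
    }
    if (s > 0) {  // undo the pool that preceded this scale
      fmat dUnpooled;
      maxpool2_back(dF, cc.pool_idx[pool_i], cc.pool_C[pool_i],
                    cc.pool_ncol_in[pool_i], dUnpooled);
      pool_i--;
      dF = std::move(dUnpooled);
    }
  }
  if (a.stem_pool) {
    fmat dUnpooled;
    maxpool2_back(dF, cc.pool_idx[pool_i], cc.pool_C[pool_i],
                  cc.pool_ncol_in[pool_i], dUnpooled);
    dF = std::move(dUnpooled);
  }
  unit_back(dF, 0, dimH[0]);  // stem; input gradient discarded

  // ---- Adam update (L2 on conv/fc weights only) --------------------------
  const float b1 = (float)beta1, b2 = (float)beta2;
  const float bc1 = 1.0f - std::pow(b1, (float)adam_t);
  const float bc2 = 1.0f - std::pow(b2, (float)adam_t);
  auto adam = [&](fmat& w, const fmat& g, fmat& m, fmat& v, bool decay) {
    fmat grad = g;
    if (decay && l2 > 0) grad += (float)l2 * w;
    m = b1 * m + (1 - b1) * grad;
    v = b2 * v + (1 - b2) * square(grad);
    w -= (float)lr * (m / bc1) / (sqrt(v / bc2) + (float)adam_eps);
  };

  List newp(params.size()), newm(adam_m.size()), newv(adam_v.size());
  for (int uu = 0; uu < U; uu++) {
    fmat mW = as_f(adam_m[3 * uu]), vW = as_f(adam_v[3 * uu]);
    adam(up[uu].W, gW[uu], mW, vW, true);
    fmat mg = as_f(adam_m[3 * uu + 1]), vg = as_f(adam_v[3 * uu + 1]);
    fmat gam(up[uu].gamma), dgm(gGamma[uu]);
    adam(gam, dgm, mg, vg, false); up[uu].gamma = gam;
    fmat mb = as_f(adam_m[3 * uu + 2]), vb = as_f(adam_v[3 * uu + 2]);
    fmat bet(up[uu].beta), dbm(gBeta[uu]);
    adam(bet, dbm, mb, vb, false); up[uu].beta = bet;
    newp[3 * uu] = as_r(up[uu].W); newm[3 * uu] = as_r(mW); newv[3 * uu] = as_r(vW);
    newp[3 * uu + 1] = as_r(up[uu].gamma); newm[3 * uu + 1] = as_r(mg); newv[3 * uu + 1] = as_r(vg);
    newp[3 * uu + 2] = as_r(up[uu].beta); newm[3 * uu + 2] = as_r(mb); newv[3 * uu + 2] = as_r(vb);
  }
  fmat mfW = as_f(adam_m[3 * U]), vfW = as_f(adam_v[3 * U]);
  adam(fcW, gfcW, mfW, vfW, true);
  fmat mfb = as_f(adam_m[3 * U + 1]), vfb = as_f(adam_v[3 * U + 1]);
  fmat fcbm(fcb), gfcbm(gfcb);
  adam(fcbm, gfcbm, mfb, vfb, false); fcb = fcbm;
  newp[3 * U] = as_r(fcW); newm[3 * U] = as_r(mfW); newv[3 * U] = as_r(vfW);
  newp[3 * U + 1] = as_r(fcb); newm[3 * U + 1] = as_r(mfb); newv[3 * U + 1] = as_r(vfb);

  List newrun(running.size());
  for (int uu = 0; uu < U; uu++) {
    newrun[2 * uu] = as_r(us[uu].rmean);
    newrun[2 * uu + 1] = as_r(us[uu].rvar);
  }

  return List::create(Rcpp::Named("params") = newp,
                      Rcpp::Named("running") = newrun,
                      Rcpp::Named("m") = newm, Rcpp::Named("v") = newv,
                      Rcpp::Named("loss") = loss,
                      Rcpp::Named("correct") = correct);
}

// Post-training batch-norm finalisation: run one train-mode forward pass
// (batch-statistic normalisation, as during optimisation) over a chunk and
// return that chunk's per-layer moments; the R side aggregates chunks into
// population statistics under the final weights.
// [[Rcpp::export]]
Rcpp::List cpp_df_bn_stats(Rcpp::List params, Rcpp::List running,
                           const arma::mat& Xr, Rcpp::List cfg) {
  Arch a = parse_arch(cfg);
  const int N = (int)Xr.n_cols, HW = a.img * a.img, Cin = a.in_channels;
  fmat X0(Cin, (uword)HW * N);
  for (int n = 0; n < N; n++)
    for (int c = 0; c < Cin; c++)
      for (int p = 0; p < HW; p++)
        X0(c, (uword)HW * n + p) = (float)Xr((uword)HW * c + p, n);
  std::vector<UnitParams> up; std::vector<UnitState> us;
  fmat fcW; fvec fcb;
  unpack(params, running, a, up, us, fcW, fcb);
  fmat gap; std::vector<int> dimH;
  forward(X0, a, up, us, fcW, fcb, N, true, nullptr, gap, dimH, 1.0f);
  const int U = (int)a.units.size();
  List newrun(2 * U);
  for (int u = 0; u < U; u++) {
    newrun[2 * u] = as_r(us[u].rmean);
    newrun[2 * u + 1] = as_r(us[u].rvar);
  }
  return newrun;
}

// [[Rcpp::export]]
arma::mat cpp_df_predict(Rcpp::List params, Rcpp::List running,
                         const arma::mat& Xr, Rcpp::List cfg,
                         int chunk = 256) {
  Arch a = parse_arch(cfg);
  const int N = (int)Xr.n_cols, HW = a.img * a.img, Cin = a.in_channels;
  std::vector<UnitParams> up; std::vector<UnitState> us;
  fmat fcW; fvec fcb;
  unpack(params, running, a, up, us, fcW, fcb);
  mat out(a.n_classes, N);
  for (int lo = 0; lo < N; lo += chunk) {
    int hi = std::min(N, lo + chunk), n = hi - lo;
    fmat X0(Cin, (uword)HW * n);
    for (int t = 0; t < n; t++)
      for (int c = 0; c < Cin; c++)
        for (int p = 0; p < HW; p++)
          X0(c, (uword)HW * t + p) = (float)Xr((uword)HW * c + p, lo + t);
    fmat gap; std::vector<int> dimH;
    fmat P = forward(X0, a, up, us, fcW, fcb, n, false, nullptr, gap, dimH);
    out.cols(lo, hi - 1) = conv_to<mat>::from(P);
  }
  return out;
}
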