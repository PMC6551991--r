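// Float-native U-Net forward/backward.
//
// The whole network state (activations, pooling indices) lives in single
// precision on the C++ side and is handed back to R as an external
// pointer, so each training step crosses the R boundary only with the
// input patch, the logits and the (small) parameter gradients.
// Convolution avoids im2col: for each of the kx*ky*kz kernel offsets the
// shifted input is a pure row-offset view of the flat (voxels x channels)
// activation matrix, so the convolution is a sum of plain sgemm calls,
// blocked along z so the accumulator stays cache-resident.  Feature maps
// are (X*Y*Z) x C column-major matrices; valid regions are cropped
// between layers.

#include <RcppArmadillo.h>
#include <vector>
using namespace Rcpp;

extern "C" void sgemm_(const char* ta, const char* tb, const int* m,
                       const int* n, const int* k, const float* alpha,
                       const float* A, const int* lda, const float* B,
                       const int* ldb, const float* beta, float* C,
                       const int* ldc);

namespace {

// C (m x n) += op(A) * op(B) on raw column-major blocks with leading
// dimensions; avoids the temporaries Armadillo makes for subview operands.
static inline void gemm_acc(char ta, char tb, int m, int n, int k,
                            const float* A, int lda, const float* B, int ldb,
                            float* C, int ldc, float beta = 1.0f) {
  const float one = 1.0f;
  sgemm_(&ta, &tb, &m, &n, &k, &one, A, &lda, B, &ldb, &beta, C, &ldc);
}

struct Dim3 { int x, y, z; long long n() const { return (long long)x * y * z; } };

struct ConvParam {
  std::vector<arma::fmat> Wo;  // one (Cin x Cout) block per kernel offset
  arma::frowvec b;
  int kx, ky, kz;
};

// weights arrive as ((kx*ky*kz*Cin) x Cout) with row index
// dx + kx*(dy + ky*(dz + kz*c))
static ConvParam unpack_conv(const NumericMatrix& W, const NumericVector& b,
                             int kx, int ky, int kz) {
  ConvParam cp;
  cp.kx = kx; cp.ky = ky; cp.kz = kz;
  const int k3 = kx * ky * kz;
  const int Cin = W.nrow() / k3;
  const int Cout = W.ncol();
  cp.Wo.resize(k3);
  for (int o = 0; o < k3; ++o) {
    arma::fmat m(Cin, Cout);
    for (int c = 0; c < Cin; ++c)
      for (int j = 0; j < Cout; ++j) m(c, j) = (float)W(o + k3 * c, j);
    cp.Wo[o] = std::move(m);
  }
  cp.b.set_size(Cout);
  for (int j = 0; j < Cout; ++j) cp.b[j] = (float)b[j];
  return cp;
}

static void pack_conv_grad(const ConvParam& g, NumericMatrix& dW, NumericVector& db) {
  const int k3 = g.kx * g.ky * g.kz;
  const int Cin = g.Wo[0].n_rows, Cout = g.Wo[0].n_cols;
  for (int o = 0; o < k3; ++o)
    for (int c = 0; c < Cin; ++c)
      for (int j = 0; j < Cout; ++j) dW(o + k3 * c, j) = g.Wo[o](c, j);
  for (int j = 0; j < Cout; ++j) db[j] = g.b[j];
}

// rows of a z-chunk in the flat full grid
static inline long long chunk_rows(const Dim3& d, int z0, int z1) {
  return (long long)d.x * d.y * (z1 - z0);
}

// Y_valid = conv(X) + b, with relu; X is (d.n() x Cin).
static arma::fmat conv_relu_fw(const arma::fmat& X, const Dim3& d,
                               const ConvParam& cp, Dim3& dout) {
  const int Cout = cp.Wo[0].n_cols;
  dout = {d.x - cp.kx + 1, d.y - cp.ky + 1, d.z - cp.kz + 1};
  arma::fmat Yfull(d.n(), Cout);
  const int zc = std::max(1, (int)(1 << 15) / (d.x * d.y));
  for (int z0 = 0; z0 < d.z; z0 += zc) {
    const int z1 = std::min(d.z, z0 + zc);
    const long long r0 = (long long)d.x * d.y * z0;
    const long long nr = chunk_rows(d, z0, z1);
    for (int dz = 0; dz < cp.kz; ++dz)
      for (int dy = 0; dy < cp.ky; ++dy)
        for (int dx = 0; dx < cp.kx; ++dx) {
          const long long off = dx + (long long)d.x * dy + (long long)d.x * d.y * dz;
          const long long nvalid = std::min(nr, d.n() - off - r0);
          if (nvalid <= 0) continue;
          const arma::fmat& Wo = cp.Wo[dx + cp.kx * (dy + cp.ky * dz)];
          const bool first = dx == 0 && dy == 0 && dz == 0;
          gemm_acc('N', 'N', (int)nvalid, Wo.n_cols, Wo.n_rows,
                   X.memptr() + r0 + off, X.n_rows,
                   Wo.memptr(), Wo.n_rows,
                   Yfull.memptr() + r0, Yfull.n_rows,
                   first ? 0.0f : 1.0f);
          if (first && nvalid < nr) {  // rows past the shifted end stay defined
            for (int j = 0; j < (int)Wo.n_cols; ++j)
              std::fill(Yfull.colptr(j) + r0 + nvalid,
                        Yfull.colptr(j) + r0 + nr, 0.0f);
          }
        }
  }
  // crop to the valid region, add bias, apply relu
  arma::fmat Y(dout.n(), Cout);
  for (int j = 0; j < Cout; ++j) {
    float* dst = Y.colptr(j);
    const float* src = Yfull.colptr(j);
    const float bj = cp.b[j];
    long long o = 0;
    for (int k = 0; k < dout.z; ++k)
      for (int jj = 0; jj < dout.y; ++jj) {
        const float* s = src + (long long)d.x * (jj + (long long)d.y * k);
        for (int i = 0; i < dout.x; ++i, ++o) {
          const float v = s[i] + bj;
          dst[o] = v > 0 ? v : 0;
        }
      }
  }
  return Y;
}

// Backward through relu+conv: given dY (valid, already relu-masked by
// caller), accumulate dW, db, and return dX (full input grid).
static arma::fmat conv_bw(const arma::fmat& X, const Dim3& d,
                          const arma::fmat& dYv, const Dim3& dout,
                          const ConvParam& cp, ConvParam& grad) {
  const int Cout = cp.Wo[0].n_cols;
  // scatter valid dY into the full grid (border rows zero)
  arma::fmat dYfull(d.n(), Cout, arma::fill::zeros);
  for (int j = 0; j < Cout; ++j) {
    float* dst = dYfull.colptr(j);
    const float* src = dYv.colptr(j);
    long long o = 0;
    for (int k = 0; k < dout.z; ++k)
      for (int jj = 0; jj < dout.y; ++jj) {
        float* s = dst + (long long)d.x * (jj + (long long)d.y * k);
        for (int i = 0; i < dout.x; ++i, ++o) s[i] = src[o];
      }
  }
  grad.kx = cp.kx; grad.ky = cp.ky; grad.kz = cp.kz;
  grad.Wo.assign(cp.Wo.size(), arma::fmat());
  for (size_t o = 0; o < cp.Wo.size(); ++o)
    grad.Wo[o].zeros(cp.Wo[o].n_rows, cp.Wo[o].n_cols);
  grad.b = arma::sum(dYv, 0);

  // weight gradients: one reduction gemm per offset over the full grid
  for (int dz = 0; dz < cp.kz; ++dz)
    for (int dy = 0; dy < cp.ky; ++dy)
      for (int dx = 0; dx < cp.kx; ++dx) {
        const long long off = dx + (long long)d.x * dy + (long long)d.x * d.y * dz;
        const long long nvalid = d.n() - off;
        const int o = dx + cp.kx * (dy + cp.ky * dz);
        const int Cin = cp.Wo[o].n_rows;
        gemm_acc('T', 'N', Cin, Cout, (int)nvalid,
                 X.memptr() + off, X.n_rows,
                 dYfull.memptr(), dYfull.n_rows,
                 grad.Wo[o].memptr(), Cin, 0.0f);
      }

  // input gradient: thin accumulating gemms per offset, chunked along z so
  // the accumulator stays cache-resident; offset 0 covers every row and
  // overwrites, the rest accumulate
  arma::fmat dX(d.n(), X.n_cols);
  const int zc2 = std::max(1, (int)(1 << 15) / (d.x * d.y));
  for (int z0 = 0; z0 < d.z; z0 += zc2) {
    const int z1 = std::min(d.z, z0 + zc2);
    const long long r0 = (long long)d.x * d.y * z0;
    const long long nr = chunk_rows(d, z0, z1);
    for (int dz = 0; dz < cp.kz; ++dz)
      for (int dy = 0; dy < cp.ky; ++dy)
        for (int dx = 0; dx < cp.kx; ++dx) {
          const long long off = dx + (long long)d.x * dy + (long long)d.x * d.y * dz;
          const long long nvalid = std::min(nr, d.n() - off - r0);
          if (nvalid <= 0) continue;
          const int o = dx + cp.kx * (dy + cp.ky * dz);
          const int Cin = cp.Wo[o].n_rows;
          gemm_acc('N', 'T', (int)nvalid, Cin, Cout,
                   dYfull.memptr() + r0, dYfull.n_rows,
                   cp.Wo[o].memptr(), Cin,
                   dX.memptr() + r0 + off, dX.n_rows,
                   o == 0 ? 0.0f : 1.0f);
        }
  }
  return dX;
}

static void relu_mask_inplace(arma::fmat& dY, const arma::fmat& Y) {
  const float* y = Y.memptr();
  float* g = dY.memptr();
  const long long n = Y.n_elem;
  for (long long i = 0; i < n; ++i) if (y[i] <= 0) g[i] = 0;
}

static arma::fmat maxpool_fw(const arma::fmat& X, const Dim3& d,
                             int fx, int fy, int fz, Dim3& dout,
                             std::vector<long long>& argmax) {
  dout = {d.x / fx, d.y / fy, d.z / fz};
  const int C = X.n_cols;
  arma::fmat Y(dout.n(), C);
  argmax.resize((size_t)dout.n() * C);
  for (int c = 0; c < C; ++c) {
    const float* x = X.colptr(c);
    float* y = Y.colptr(c);
    long long o = 0;
    for (int k = 0; k < dout.z; ++k)
      for (int j = 0; j < dout.y; ++j)
        for (int i = 0; i < dout.x; ++i, ++o) {
          float best = -1e30f; long long bi = -1;
          for (int dz = 0; dz < fz; ++dz)
            for (int dy = 0; dy < fy; ++dy)
              for (int dx = 0; dx < fx; ++dx) {
                const long long ix = (long long)(i * fx + dx) +
                  (long long)d.x * ((j * fy + dy) + (long long)d.y * (k * fz + dz));
                if (x[ix] > best) { best = x[ix]; bi = ix; }
              }
          y[o] = best;
          argmax[(size_t)dout.n() * c + o] = bi;
        }
  }
  return Y;
}

static arma::fmat maxpool_bw(const arma::fmat& dY, const Dim3& din, const Dim3& dout,
                             int C, const std::vector<long long>& argmax) {
  arma::fmat dX(din.n(), C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    float* dst = dX.colptr(c);
    const float* g = dY.colptr(c);
    for (long long o = 0; o < dout.n(); ++o)
      dst[argmax[(size_t)dout.n() * c + o]] += g[o];
  }
  return dX;
}

static arma::fmat upsample_fw(const arma::fmat& X, const Dim3& d,
                              int fx, int fy, int fz, Dim3& dout) {
  dout = {d.x * fx, d.y * fy, d.z * fz};
  const int C = X.n_cols;
  arma::fmat Y(dout.n(), C);
  for (int c = 0; c < C; ++c) {
    const float* x = X.colptr(c);
    float* y = Y.colptr(c);
    long long o = 0;
    for (int k = 0; k < dout.z; ++k)
      for (int j = 0; j < dout.y; ++j)
        for (int i = 0; i < dout.x; ++i, ++o)
          y[o] = x[(long long)(i / fx) +
                   (long long)d.x * ((j / fy) + (long long)d.y * (k / fz))];
  }
  return Y;
}

static arma::fmat upsample_bw(const arma::fmat& dY, const Dim3& din, const Dim3& dout,
                              int fx, int fy, int fz) {
  const int C = dY.n_cols;
  arma::fmat dX(din.n(), C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    float* dst = dX.colptr(c);
    const float* g = dY.colptr(c);
    long long o = 0;
    for (int k = 0; k < dout.z; ++k)
      for (int j = 0; j < dout.y; ++j)
        for (int i = 0; i < dout.x; ++i, ++o)
          dst[(long long)(i / fx) +
              (long long)din.x * ((j / fy) + (long long)din.y * (k / fz))] += g[o];
  }
  return dX;
}

static arma::fmat crop_center(const arma::fmat& X, const Dim3& d, const Dim3& t) {
  const int ox = (d.x - t.x) / 2, oy = (d.y - t.y) / 2, oz = (d.z - t.z) / 2;
  const int C = X.n_cols;
  arma::fmat Y(t.n(), C);
  for (int c = 0; c < C; ++c) {
    const float* x = X.colptr(c);
    float* y = Y.colptr(c);
    long long o = 0;
    for (int k = 0; k < t.z; ++k)
      for (int j = 0; j < t.y; ++j)
        for (int i = 0; i < t.x; ++i, ++o)
          y[o] = x[(long long)(i + ox) +
                   (long long)d.x * ((j + oy) + (long long)d.y * (k + oz))];
  }
  return Y;
}

static arma::fmat pad_center(const arma::fmat& dY, const Dim3& t, const Dim3& d) {
  const int ox = (d.x - t.x) / 2, oy = (d.y - t.y) / 2, oz = (d.z - t.z) / 2;
  const int C = dY.n_cols;
  arma::fmat dX(d.n(), C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    float* x = dX.colptr(c);
    const float* y = dY.colptr(c);
    long long o = 0;
    for (int k = 0; k < t.z; ++k)
      for (int j = 0; j < t.y; ++j)
        for (int i = 0; i < t.x; ++i, ++o)
          x[(long long)(i + ox) +
            (long long)d.x * ((j + oy) + (long long)d.y * (k + oz))] = y[o];
  }
  return dX;
}

struct UnetCache {
  int depth;
  Dim3 din;
  std::vector<arma::fmat> a_in, a1, a2;         // analysis per level
  std::vector<Dim3> d_in, d_a1, d_a2, d_pool;
  std::vector<std::vector<long long>> poolidx;
  std::vector<arma::fmat> s_cat, s1, s2;        // synthesis per level
  std::vector<Dim3> d_cat, d_s1, d_s2, d_up;
  std::vector<int> skip_ch;
  arma::fmat last;
  Dim3 d_last;
};

static ConvParam get_conv(const List& params, const std::string& w,
                          const std::string& b, int kx, int ky, int kz) {
  return unpack_conv(as<NumericMatrix>(params[w]), as<NumericVector>(params[b]),
                     kx, ky, kz);
}

}  // namespace

// [[Rcpp::export]]
List cpp_unet_fw(List params, NumericVector x, List cfg) {
  const int depth = as<int>(cfg["depth"]);
  IntegerVector kern = cfg["kernel"], pool = cfg["pool"];
  const int kx = kern[0], ky = kern[1], kz = kern[2];
  const int fx = pool[0], fy = pool[1], fz = pool[2];

  IntegerVector xd(x.attr("dim"));
  const int C0 = (xd.size() > 3) ? xd[3] : 1;
  Dim3 d = {xd[0], xd[1], xd[2]};
  arma::fmat cur(d.n(), C0);
  for (long long i = 0; i < (long long)x.size(); ++i) cur.memptr()[i] = (float)x[i];

  Rcpp::XPtr<UnetCache> cache(new UnetCache(), true);
  cache->depth = depth;
  cache->din = d;
  cache->a_in.resize(depth); cache->a1.resize(depth); cache->a2.resize(depth);
  cache->d_in.resize(depth); cache->d_a1.resize(depth); cache->d_a2.resize(depth);
  cache->d_pool.resize(depth); cache->poolidx.resize(depth);
  const int ns = std::max(depth - 1, 0);
  cache->s_cat.resize(ns); cache->s1.resize(ns); cache->s2.resize(ns);
  cache->d_cat.resize(ns); cache->d_s1.resize(ns); cache->d_s2.resize(ns);
  cache->d_up.resize(ns); cache->skip_ch.resize(ns);

  char nm[32];
  for (int l = 0; l < depth; ++l) {
    cache->a_in[l] = std::move(cur);
    cache->d_in[l] = d;
    snprintf(nm, sizeof nm, "a%d.W1", l + 1);
    std::string w1 = nm; snprintf(nm, sizeof nm, "a%d.b1", l + 1);
    ConvParam c1 = get_conv(params, w1, nm, kx, ky, kz);
    Dim3 d1; cache->a1[l] = conv_relu_fw(cache->a_in[l], d, c1, d1);
    cache->d_a1[l] = d1;
    snprintf(nm, sizeof nm, "a%d.W2", l + 1);
    std::string w2 = nm; snprintf(nm, sizeof nm, "a%d.b2", l + 1);
    ConvParam c2 = get_conv(params, w2, nm, kx, ky, kz);
    Dim3 d2; cache->a2[l] = conv_relu_fw(cache->a1[l], d1, c2, d2);
    cache->d_a2[l] = d2;
    if (l < depth - 1) {
      Dim3 dp;
      cur = maxpool_fw(cache->a2[l], d2, fx, fy, fz, dp, cache->poolidx[l]);
      cache->d_pool[l] = dp;
      d = dp;
    } else {
      cur = cache->a2[l];
      d = d2;
    }
  }
  for (int l = depth - 2; l >= 0; --l) {
    Dim3 dup;
    arma::fmat up = upsample_fw(cur, d, fx, fy, fz, dup);
    cache->d_up[l] = dup;
    arma::fmat skc = crop_center(cache->a2[l], cache->d_a2[l], dup);
    cache->skip_ch[l] = skc.n_cols;
    cache->s_cat[l] = arma::join_rows(skc, up);
    cache->d_cat[l] = dup;
    snprintf(nm, sizeof nm, "s%d.W1", l + 1);
    std::string w1 = nm; snprintf(nm, sizeof nm, "s%d.b1", l + 1);
    ConvParam c1 = get_conv(params, w1, nm, kx, ky, kz);
    Dim3 d1; cache->s1[l] = conv_relu_fw(cache->s_cat[l], dup, c1, d1);
    cache->d_s1[l] = d1;
    snprintf(nm, sizeof nm, "s%d.W2", l + 1);
    std::string w2 = nm; snprintf(nm, sizeof nm, "s%d.b2", l + 1);
    ConvParam c2 = get_conv(params, w2, nm, kx, ky, kz);
    Dim3 d2; cache->s2[l] = conv_relu_fw(cache->s1[l], d1, c2, d2);
    cache->d_s2[l] = d2;
    cur = cache->s2[l];
    d = d2;
  }
  cache->last = std::move(cur);
  cache->d_last = d;

  // final 1x1x1 convolution (no relu)
  ConvParam cf = get_conv(params, "final.W", "final.b", 1, 1, 1);
  const int K = cf.Wo[0].n_cols;
  arma::fmat logits = cache->last * cf.Wo[0];
  logits.each_row() += cf.b;

  NumericVector out((R_xlen_t)d.n() * K);
  out.attr("dim") = IntegerVector::create(d.x, d.y, d.z, K);
  for (long long i = 0; i < (long long)out.size(); ++i)
    out[i] = (double)logits.memptr()[i];
  return List::create(_["logits"] = out, _["cache"] = cache);
}

// Explicitly free a forward cache (used by inference paths that never run
// the backward pass).
// [[Rcpp::export]]
void cpp_unet_release(SEXP cacheptr) {
  Rcpp::XPtr<UnetCache> cache(cacheptr);
  *cache = UnetCache();
}

// [[Rcpp::export]]
List cpp_unet_bw(List params, SEXP cacheptr, NumericVector dlogits, List cfg) {
  Rcpp::XPtr<UnetCache> cache(cacheptr);
  const int depth = cache->depth;
  IntegerVector kern = cfg["kernel"], pool = cfg["pool"];
  const int kx = kern[0], ky = kern[1], kz = kern[2];
  const int fx = pool[0], fy = pool[1], fz = pool[2];
  List grads;
  char nm[32];

  IntegerVector dd(dlogits.attr("dim"));
  const int K = dd[3];
  arma::fmat dlog(cache->d_last.n(), K);
  for (long long i = 0; i < (long long)dlogits.size(); ++i)
    dlog.memptr()[i] = (float)dlogits[i];

  ConvParam cf = get_conv(params, "final.W", "final.b", 1, 1, 1);
  {
    arma::fmat dWf = cache->last.t() * dlog;  // (C x K)
    NumericMatrix dW(dWf.n_rows, K);
    for (int c = 0; c < (int)dWf.n_rows; ++c)
      for (int j = 0; j < K; ++j) dW(c, j) = dWf(c, j);
    NumericVector db(K);
    arma::frowvec dbf = arma::sum(dlog, 0);
    for (int j = 0; j < K; ++j) db[j] = dbf[j];
    grads["final.W"] = dW; grads["final.b"] = db;
  }
  arma::fmat d_cur = dlog * cf.Wo[0].t();

  auto conv_pair_bw = [&](const char* prefix, int l, const arma::fmat& in1,
                          const Dim3& din1, const arma::fmat& y1, const Dim3& dy1,
                          const arma::fmat& y2, const Dim3& dy2,
                          arma::fmat& dY2) -> arma::fmat {
    snprintf(nm, sizeof nm, "%s%d.W2", prefix, l + 1);
    std::string w2 = nm; snprintf(nm, sizeof nm, "%s%d.b2", prefix, l + 1);
    std::string b2 = nm;
    snprintf(nm, sizeof nm, "%s%d.W1", prefix, l + 1);
    std::string w1 = nm; snprintf(nm, sizeof nm, "%s%d.b1", prefix, l + 1);
    std::string b1 = nm;
    ConvParam c2 = get_conv(params, w2, b2, kx, ky, kz);
    ConvParam c1 = get_conv(params, w1, b1, kx, ky, kz);
    relu_mask_inplace(dY2, y2);
    ConvParam g2;
    arma::fmat dY1 = conv_bw(y1, dy1, dY2, dy2, c2, g2);
    relu_mask_inplace(dY1, y1);
    ConvParam g1;
    arma::fmat dIn = conv_bw(in1, din1, dY1, dy1, c1, g1);
    NumericMatrix dW2(c2.Wo.size() * c2.Wo[0].n_rows, c2.Wo[0].n_cols);
    NumericVector db2(c2.Wo[0].n_cols);
    pack_conv_grad(g2, dW2, db2);
    NumericMatrix dW1(c1.Wo.size() * c1.Wo[0].n_rows, c1.Wo[0].n_cols);
    NumericVector db1(c1.Wo[0].n_cols);
    pack_conv_grad(g1, dW1, db1);
    grads[w2] = dW2; grads[b2] = db2;
    grads[w1] = dW1; grads[b1] = db1;
    return dIn;
  };

  std::vector<arma::fmat> dskip(std::max(depth - 1, 0));
  for (int l = 0; l < depth - 1; ++l) {
    // d_cur is the gradient at s2[l] (valid grid d_s2[l])
    arma::fmat dcat = conv_pair_bw("s", l, cache->s_cat[l], cache->d_cat[l],
                                   cache->s1[l], cache->d_s1[l],
                                   cache->s2[l], cache->d_s2[l], d_cur);
    const int nsk = cache->skip_ch[l];
    arma::fmat dskc = dcat.cols(0, nsk - 1);
    arma::fmat dup = dcat.cols(nsk, dcat.n_cols - 1);
    dskip[l] = pad_center(dskc, cache->d_cat[l], cache->d_a2[l]);
    d_cur = upsample_bw(dup, (l == depth - 2) ? cache->d_a2[depth - 1]
                                              : cache->d_s2[l + 1],
                        cache->d_up[l], fx, fy, fz);
  }
  for (int l = depth - 1; l >= 0; --l) {
    arma::fmat dA2;
    if (l < depth - 1) {
      dA2 = maxpool_bw(d_cur, cache->d_a2[l], cache->d_pool[l],
                       cache->a2[l].n_cols, cache->poolidx[l]);
      dA2 += dskip[l];
    } else {
      dA2 = std::move(d_cur);
    }
    d_cur = conv_pair_bw("a", l, cache->a_in[l], cache->d_in[l],
                         cache->a1[l], cache->d_a1[l],
                         cache->a2[l], cache->d_a2[l], dA2);
  }
  // backward consumes the cache: release the float activation state now
  // rather than waiting for R's garbage collector (it cannot see C++
  // allocations, so deferred release balloons the footprint during training)
  *cache = UnetCache();
  return grads;
}


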