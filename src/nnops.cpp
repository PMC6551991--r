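// Neural-network primitives for the valid-convolution U-Nets.
//
// Feature maps are R numeric arrays with dim (X, Y, Z, C); a missing fourth
// dimension is treated as C = 1.  Convolution weights are matrices of shape
// (kx*ky*kz*Cin) x Cout with row index dx + kx*(dy + ky*(dz + kz*c)).
// All heavy arithmetic runs in single precision through BLAS gemm on an
// im2col matrix built slab-by-slab along z, which bounds peak memory.

#include <RcppArmadillo.h>
#include <cstring>
using namespace Rcpp;

static inline void get_dims4(const NumericVector& x, int& X, int& Y, int& Z, int& C) {
  IntegerVector d(x.attr("dim"));
  if (d.size() < 3) stop("expected an array with >= 3 dimensions");
  X = d[0]; Y = d[1]; Z = d[2];
  C = (d.size() > 3) ? d[3] : 1;
}

static arma::fvec to_float(const NumericVector& x) {
  arma::fvec out(x.size());
  const double* p = REAL(x);
  for (R_xlen_t i = 0; i < x.size(); ++i) out[i] = (float)p[i];
  return out;
}

// Fill the transposed im2col matrix Kt (ncols x krows) for output slabs
// z0..z1-1.  Column r of Kt holds, for every output voxel of the slab, the
// input value at kernel offset r.
static void fill_im2col(const arma::fvec& xf, int X, int Y, int Z, int C,
                        int kx, int ky, int kz,
                        int Xo, int Yo, int z0, int z1, arma::fmat& Kt) {
  const int slab = z1 - z0;
  const long long ncols = (long long)Xo * Yo * slab;
  for (int c = 0; c < C; ++c) {
    for (int dz = 0; dz < kz; ++dz) {
      for (int dy = 0; dy < ky; ++dy) {
        for (int dx = 0; dx < kx; ++dx) {
          const int r = dx + kx * (dy + ky * (dz + kz * c));
          float* dst = Kt.colptr(r);
          for (int zo = z0; zo < z1; ++zo) {
            for (int yo = 0; yo < Yo; ++yo) {
              const long long src = (long long)dx +
                (long long)X * ((yo + dy) + (long long)Y * ((zo + dz) + (long long)Z * c));
              const long long off = (long long)Xo * (yo + (long long)Yo * (zo - z0));
              std::memcpy(dst + off, xf.memptr() + src, sizeof(float) * Xo);
            }
          }
          (void)ncols;
        }
      }
    }
  }
}

static int slab_size(int Xo, int Yo) {
  const long long target = 1LL << 15;  // ~32k output voxels per gemm call
  long long s = target / ((long long)Xo * Yo);
  if (s < 1) s = 1;
  return (int)s;
}

// [[Rcpp::export]]
NumericVector cpp_conv3d_fw(NumericVector x, NumericMatrix W, NumericVector b,
                            int kx, int ky, int kz) {
  int X, Y, Z, C; get_dims4(x, X, Y, Z, C);
  const int Xo = X - kx + 1, Yo = Y - ky + 1, Zo = Z - kz + 1;
  if (Xo < 1 || Yo < 1 || Zo < 1) stop("input smaller than kernel");
  const int Cout = W.ncol();
  const int krows = kx * ky * kz * C;
  if (W.nrow() != krows) stop("weight rows (%d) do not match kernel*channels (%d)", W.nrow(), krows);
  if (b.size() != Cout) stop("bias length mismatch");

  arma::fvec xf = to_float(x);
  arma::fmat Wf(krows, Cout);
  for (int j = 0; j < Cout; ++j)
    for (int i = 0; i < krows; ++i) Wf(i, j) = (float)W(i, j);
  arma::fvec bf(Cout);
  for (int j = 0; j < Cout; ++j) bf[j] = (float)b[j];

  NumericVector out((R_xlen_t)Xo * Yo * Zo * Cout);
  out.attr("dim") = IntegerVector::create(Xo, Yo, Zo, Cout);
  double* op = REAL(out);

  const int slab = slab_size(Xo, Yo);
  arma::fmat Kt((long long)Xo * Yo * slab, krows);
  for (int z0 = 0; z0 < Zo; z0 += slab) {
    const int z1 = std::min(Zo, z0 + slab);
    const long long ncols = (long long)Xo * Yo * (z1 - z0);
    if ((long long)Kt.n_rows != ncols) Kt.set_size(ncols, krows);
    fill_im2col(xf, X, Y, Z, C, kx, ky, kz, Xo, Yo, z0, z1, Kt);
    arma::fmat O = Kt * Wf;  // ncols x Cout
    for (int j = 0; j < Cout; ++j) {
      const float* src = O.colptr(j);
      double* dst = op + (long long)Xo * Yo * z0 + (long long)Xo * Yo * Zo * j;
      for (long long i = 0; i < ncols; ++i) dst[i] = (double)(src[i] + bf[j]);
    }
  }
  return out;
}

// [[Rcpp::export]]
List cpp_conv3d_bw(NumericVector x, NumericMatrix W, NumericVector dy,
                   int kx, int ky, int kz) {
  int X, Y, Z, C; get_dims4(x, X, Y, Z, C);
  const int Xo = X - kx + 1, Yo = Y - ky + 1, Zo = Z - kz + 1;
  const int Cout = W.ncol();
  const int krows = kx * ky * kz * C;
  if (W.nrow() != krows) stop("weight shape mismatch");
  if (dy.size() != (R_xlen_t)Xo * Yo * Zo * Cout) stop("gradient shape mismatch");

  arma::fvec xf = to_float(x);
  arma::fvec dyf = to_float(dy);
  arma::fmat Wf(krows, Cout);
  for (int j = 0; j < Cout; ++j)
    for (int i = 0; i < krows; ++i) Wf(i, j) = (float)W(i, j);

  arma::fmat dWf(krows, Cout, arma::fill::zeros);
  arma::fvec dbf(Cout, arma::fill::zeros);
  arma::fvec dxf(xf.n_elem, arma::fill::zeros);

  const int slab = slab_size(Xo, Yo);
  arma::fmat Kt, dOut, dKt;
  for (int z0 = 0; z0 < Zo; z0 += slab) {
    const int z1 = std::min(Zo, z0 + slab);
    const long long ncols = (long long)Xo * Yo * (z1 - z0);
    Kt.set_size(ncols, krows);
    fill_im2col(xf, X, Y, Z, C, kx, ky, kz, Xo, Yo, z0, z1, Kt);
    dOut.set_size(ncols, Cout);
    for (int j = 0; j < Cout; ++j) {
      const float* src = dyf.memptr() + (long long)Xo * Yo * z0 + (long long)Xo * Yo * Zo * j;
      std::memcpy(dOut.colptr(j), src, sizeof(float) * ncols);
    }
    dWf += Kt.t() * dOut;
    dbf += arma::sum(dOut, 0).t();
    dKt = dOut * Wf.t();  // ncols x krows
    for (int c = 0; c < C; ++c) {
      for (int dz = 0; dz < kz; ++dz) {
        for (int dyk = 0; dyk < ky; ++dyk) {
          for (int dxk = 0; dxk < kx; ++dxk) {
            const int r = dxk + kx * (dyk + ky * (dz + kz * c));
            const float* src = dKt.colptr(r);
            for (int zo = z0; zo < z1; ++zo) {
              for (int yo = 0; yo < Yo; ++yo) {
                float* dst = dxf.memptr() + (long long)dxk +
                  (long long)X * ((yo + dyk) + (long long)Y * ((zo + dz) + (long long)Z * c));
                const float* s = src + (long long)Xo * (yo + (long long)Yo * (zo - z0));
                for (int i = 0; i < Xo; ++i) dst[i] += s[i];
              }
            }
          }
        }
      }
    }
  }

  NumericVector dx(x.size());
  dx.attr("dim") = x.attr("dim");
  for (R_xlen_t i = 0; i < dx.size(); ++i) dx[i] = (double)dxf[i];
  NumericMatrix dW(krows, Cout);
  for (int j = 0; j < Cout; ++j)
    for (int i = 0; i < krows; ++i) dW(i, j) = (double)dWf(i, j);
  NumericVector db(Cout);
  for (int j = 0; j < Cout; ++j) db[j] = (double)dbf[j];
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}

// [[Rcpp::export]]
NumericVector cpp_relu_fw(NumericVector x) {
  NumericVector y = clone(x);
  double* p = REAL(y);
  for (R_xlen_t i = 0; i < y.size(); ++i) if (p[i] < 0) p[i] = 0;
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_relu_bw(NumericVector y, NumericVector dy) {
  if (y.size() != dy.size()) stop("relu gradient shape mismatch");
  NumericVector dx = clone(dy);
  const double* py = REAL(y);
  double* p = REAL(dx);
  for (R_xlen_t i = 0; i < dx.size(); ++i) if (py[i] <= 0) p[i] = 0;
  return dx;
}

// [[Rcpp::export]]
List cpp_maxpool_fw(NumericVector x, int fx, int fy, int fz) {
  int X, Y, Z, C; get_dims4(x, X, Y, Z, C);
  if (X % fx || Y % fy || Z % fz) stop("pooling requires divisible extents");
  const int Xo = X / fx, Yo = Y / fy, Zo = Z / fz;
  NumericVector y((R_xlen_t)Xo * Yo * Zo * C);
  y.attr("dim") = IntegerVector::create(Xo, Yo, Zo, C);
  IntegerVector am(y.size());
  const double* px = REAL(x);
  double* py = REAL(y);
  int* pa = INTEGER(am);
  R_xlen_t o = 0;
  for (int c = 0; c < C; ++c)
    for (int zo = 0; zo < Zo; ++zo)
      for (int yo = 0; yo < Yo; ++yo)
        for (int xo = 0; xo < Xo; ++xo, ++o) {
          double best = -INFINITY; long long bi = -1;
          for (int dz = 0; dz < fz; ++dz)
            for (int dy = 0; dy < fy; ++dy)
              for (int dx = 0; dx < fx; ++dx) {
                const long long i = (long long)(xo * fx + dx) +
                  (long long)X * ((yo * fy + dy) +
                  (long long)Y * ((zo * fz + dz) + (long long)Z * c));
                if (px[i] > best) { best = px[i]; bi = i; }
              }
          py[o] = best;
          pa[o] = (int)bi;
        }
  return List::create(_["y"] = y, _["argmax"] = am);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bw(IntegerVector argmax, NumericVector dy, IntegerVector xdim) {
  R_xlen_t n = 1;
  for (int i = 0; i < xdim.size(); ++i) n *= xdim[i];
  NumericVector dx(n);
  dx.attr("dim") = xdim;
  double* p = REAL(dx);
  const double* pd = REAL(dy);
  const int* pa = INTEGER(argmax);
  for (R_xlen_t i = 0; i < dy.size(); ++i) p[pa[i]] += pd[i];
  return dx;
}

// [[Rcpp::export]]
NumericVector cpp_upsample_fw(NumericVector x, int fx, int fy, int fz) {
  int X, Y, Z, C; get_dims4(x, X, Y, Z, C);
  const int Xo = X * fx, Yo = Y * fy, Zo = Z * fz;
  NumericVector y((R_xlen_t)Xo * Yo * Zo * C);
  y.attr("dim") = IntegerVector::create(Xo, Yo, Zo, C);
  const double* px = REAL(x);
  double* py = REAL(y);
  R_xlen_t o = 0;
  for (int c = 0; c < C; ++c)
    for (int zo = 0; zo < Zo; ++zo)
      for (int yo = 0; yo < Yo; ++yo)
        for (int xo = 0; xo < Xo; ++xo, ++o) {
          const long long i = (long long)(xo / fx) +
            (long long)X * ((yo / fy) + (long long)Y * ((zo / fz) + (long long)Z * c));
          py[o] = px[i];
        }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_upsample_bw(NumericVector dy, int fx, int fy, int fz) {
  int Xo, Yo, Zo, C; get_dims4(dy, Xo, Yo, Zo, C);
  if (Xo % fx || Yo % fy || Zo % fz) stop("upsample gradient shape mismatch");
  const int X = Xo / fx, Y = Yo / fy, Z = Zo / fz;
  NumericVector dx((R_xlen_t)X * Y * Z * C);
  dx.attr("dim") = IntegerVector::create(X, Y, Z, C);
  const double* pd = REAL(dy);
  double* p = REAL(dx);
  R_xlen_t o = 0;
  for (int c = 0; c < C; ++c)
    for (int zo = 0; zo < Zo; ++zo)
      for (int yo = 0; yo < Yo; ++yo)
        for (int xo = 0; xo < Xo; ++xo, ++o) {
          const long long i = (long long)(xo / fx) +
            (long long)X * ((yo / fy) + (long long)Y * ((zo / fz) + (long long)Z * c));
          p[i] += pd[o];
        }
  return dx;
}

// [[Rcpp::export]]
NumericVector cpp_crop_center(NumericVector x, int tx, int ty, int tz) {
  int X, Y, Z, C; get_dims4(x, X, Y, Z, C);
  if (tx > X || ty > Y || tz > Z) stop("crop larger than input");
  const int ox = (X - tx) / 2, oy = (Y - ty) / 2, oz = (Z - tz) / 2;
  NumericVector y((R_xlen_t)tx * ty * tz * C);
  y.attr("dim") = IntegerVector::create(tx, ty, tz, C);
  const double* px = REAL(x);
  double* py = REAL(y);
  for (int c = 0; c < C; ++c)
    for (int z = 0; z < tz; ++z)
      for (int yy = 0; yy < ty; ++yy) {
        const long long src = (long long)ox +
          (long long)X * ((yy + oy) + (long long)Y * ((z + oz) + (long long)Z * c));
        const long long dst = (long long)tx * (yy + (long long)ty * (z + (long long)tz * c));
        std::memcpy(py + dst, px + src, sizeof(double) * tx);
      }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_pad_center(NumericVector dy, int X, int Y, int Z) {
  int tx, ty, tz, C; get_dims4(dy, tx, ty, tz, C);
  const int ox = (X - tx) / 2, oy = (Y - ty) / 2, oz = (Z - tz) / 2;
  NumericVector dx((R_xlen_t)X * Y * Z * C);
  dx.attr("dim") = IntegerVector::create(X, Y, Z, C);
  const double* pd = REAL(dy);
  double* p = REAL(dx);
  for (int c = 0; c < C; ++c)
    for (int z = 0; z < tz; ++z)
      for (int yy = 0; yy < ty; ++yy) {
        const long long dst = (long long)ox +
          (long long)X * ((yy + oy) + (long long)Y * ((z + oz) + (long long)Z * c));
        const long long src = (long long)tx * (yy + (long long)ty * (z + (long long)tz * c));
        std::memcpy(p + dst, pd + src, sizeof(double) * tx);
      }
  return dx;
}

// Softmax over the channel dimension.
// [[Rcpp::export]]
NumericVector cpp_softmax(NumericVector logits) {
  int X, Y, Z, K; get_dims4(logits, X, Y, Z, K);
  const R_xlen_t n = (R_xlen_t)X * Y * Z;
  NumericVector probs(clone(logits));
  double* p = REAL(probs);
  for (R_xlen_t v = 0; v < n; ++v) {
    double m = -INFINITY;
    for (int k = 0; k < K; ++k) m = std::max(m, p[v + n * k]);
    double s = 0;
    for (int k = 0; k < K; ++k) { p[v + n * k] = std::exp(p[v + n * k] - m); s += p[v + n * k]; }
    for (int k = 0; k < K; ++k) p[v + n * k] /= s;
  }
  return probs;
}

// Mean categorical cross entropy with gradient; labels are 0-based class
// indices per voxel, -1 marks voxels excluded from the loss.
// [[Rcpp::export]]
List cpp_softmax_ce(NumericVector logits, IntegerVector labels) {
  int X, Y, Z, K; get_dims4(logits, X, Y, Z, K);
  const R_xlen_t n = (R_xlen_t)X * Y * Z;
  if (labels.size() != n) stop("label count mismatch");
  NumericVector grad(clone(logits));
  double* g = REAL(grad);
  const int* lab = INTEGER(labels);
  double loss = 0;
  R_xlen_t nval = 0;
  for (R_xlen_t v = 0; v < n; ++v) if (lab[v] >= 0) ++nval;
  if (nval == 0) stop("no labelled voxels");
  for (R_xlen_t v = 0; v < n; ++v) {
    double m = -INFINITY;
    for (int k = 0; k < K; ++k) m = std::max(m, g[v + n * k]);
    double s = 0;
    for (int k = 0; k < K; ++k) s += std::exp(g[v + n * k] - m);
    const double lse = m + std::log(s);
    if (lab[v] < 0) {
      for (int k = 0; k < K; ++k) g[v + n * k] = 0;
      continue;
    }
    if (lab[v] >= K) stop("label out of range");
    loss += (lse - g[v + n * lab[v]]) / nval;
    for (int k = 0; k < K; ++k) {
      double p = std::exp(g[v + n * k] - lse);
      g[v + n * k] = (p - (k == lab[v] ? 1.0 : 0.0)) / nval;
    }
  }
  return List::create(_["loss"] = loss, _["grad"] = grad);
}
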