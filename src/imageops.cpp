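// Volume-processing primitives: affine resampling, binary morphology,
// connected-component labelling, and separable Gaussian smoothing.
// Volumes are R numeric/logical arrays with dim (X, Y, Z).

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline void get_dims3(SEXP x, int& X, int& Y, int& Z) {
  IntegerVector d(Rf_getAttrib(x, R_DimSymbol));
  if (d.size() != 3) stop("expected a 3D array");
  X = d[0]; Y = d[1]; Z = d[2];
}

// Resample src on a destination grid.  M is a 3x4 matrix mapping 0-based
// destination voxel indices to 0-based source voxel coordinates.
// mode 0 = trilinear, 1 = nearest neighbour.  Out-of-field voxels get `oob`.
// [[Rcpp::export]]
NumericVector cpp_resample_affine(NumericVector src, NumericMatrix M,
                                  IntegerVector dstdim, int mode, double oob) {
  int X, Y, Z; get_dims3(src, X, Y, Z);
  const int DX = dstdim[0], DY = dstdim[1], DZ = dstdim[2];
  NumericVector out((R_xlen_t)DX * DY * DZ);
  out.attr("dim") = IntegerVector::create(DX, DY, DZ);
  const double* s = REAL(src);
  double* o = REAL(out);
  const double m00 = M(0,0), m01 = M(0,1), m02 = M(0,2), m03 = M(0,3);
  const double m10 = M(1,0), m11 = M(1,1), m12 = M(1,2), m13 = M(1,3);
  const double m20 = M(2,0), m21 = M(2,1), m22 = M(2,2), m23 = M(2,3);
  R_xlen_t idx = 0;
  for (int k = 0; k < DZ; ++k)
    for (int j = 0; j < DY; ++j)
      for (int i = 0; i < DX; ++i, ++idx) {
        const double sx = m00*i + m01*j + m02*k + m03;
        const double sy = m10*i + m11*j + m12*k + m13;
        const double sz = m20*i + m21*j + m22*k + m23;
        if (mode == 1) {
          const int ix = (int)std::lround(sx), iy = (int)std::lround(sy), iz = (int)std::lround(sz);
          if (ix < 0 || iy < 0 || iz < 0 || ix >= X || iy >= Y || iz >= Z) { o[idx] = oob; continue; }
          o[idx] = s[(R_xlen_t)ix + (R_xlen_t)X * (iy + (R_xlen_t)Y * iz)];
        } else {
          if (sx < 0 || sy < 0 || sz < 0 || sx > X - 1 || sy > Y - 1 || sz > Z - 1) { o[idx] = oob; continue; }
          const int x0 = (int)std::floor(sx), y0 = (int)std::floor(sy), z0 = (int)std::floor(sz);
          const int x1 = std::min(x0 + 1, X - 1), y1 = std::min(y0 + 1, Y - 1), z1 = std::min(z0 + 1, Z - 1);
          const double fx = sx - x0, fy = sy - y0, fz = sz - z0;
          double v = 0;
          for (int dz = 0; dz < 2; ++dz)
            for (int dy = 0; dy < 2; ++dy)
              for (int dx = 0; dx < 2; ++dx) {
                const double w = (dx ? fx : 1 - fx) * (dy ? fy : 1 - fy) * (dz ? fz : 1 - fz);
                if (w == 0) continue;
                const int xi = dx ? x1 : x0, yi = dy ? y1 : y0, zi = dz ? z1 : z0;
                v += w * s[(R_xlen_t)xi + (R_xlen_t)X * (yi + (R_xlen_t)Y * zi)];
              }
          o[idx] = v;
        }
      }
  return out;
}

// Resample src at a fixed list of 0-based destination voxel indices
// (3 x N matrix `pts`), through the same dst-voxel -> src-voxel map M.
// [[Rcpp::export]]
NumericVector cpp_resample_points(NumericVector src, NumericMatrix M,
                                  IntegerMatrix pts, int mode, double oob) {
  int X, Y, Z; get_dims3(src, X, Y, Z);
  const int N = pts.ncol();
  NumericVector out(N);
  const double* s = REAL(src);
  const double m00 = M(0,0), m01 = M(0,1), m02 = M(0,2), m03 = M(0,3);
  const double m10 = M(1,0), m11 = M(1,1), m12 = M(1,2), m13 = M(1,3);
  const double m20 = M(2,0), m21 = M(2,1), m22 = M(2,2), m23 = M(2,3);
  for (int n = 0; n < N; ++n) {
    const int i = pts(0, n), j = pts(1, n), k = pts(2, n);
    const double sx = m00*i + m01*j + m02*k + m03;
    const double sy = m10*i + m11*j + m12*k + m13;
    const double sz = m20*i + m21*j + m22*k + m23;
    if (mode == 1) {
      const int ix = (int)std::lround(sx), iy = (int)std::lround(sy), iz = (int)std::lround(sz);
      if (ix < 0 || iy < 0 || iz < 0 || ix >= X || iy >= Y || iz >= Z) { out[n] = oob; continue; }
      out[n] = s[(R_xlen_t)ix + (R_xlen_t)X * (iy + (R_xlen_t)Y * iz)];
    } else {
      if (sx < 0 || sy < 0 || sz < 0 || sx > X - 1 || sy > Y - 1 || sz > Z - 1) { out[n] = oob; continue; }
      const int x0 = (int)std::floor(sx), y0 = (int)std::floor(sy), z0 = (int)std::floor(sz);
      const int x1 = std::min(x0 + 1, X - 1), y1 = std::min(y0 + 1, Y - 1), z1 = std::min(z0 + 1, Z - 1);
      const double fx = sx - x0, fy = sy - y0, fz = sz - z0;
      double v = 0;
      for (int dz = 0; dz < 2; ++dz)
        for (int dy = 0; dy < 2; ++dy)
          for (int dx = 0; dx < 2; ++dx) {
            const double w = (dx ? fx : 1 - fx) * (dy ? fy : 1 - fy) * (dz ? fz : 1 - fz);
            if (w == 0) continue;
            const int xi = dx ? x1 : x0, yi = dy ? y1 : y0, zi = dz ? z1 : z0;
            v += w * s[(R_xlen_t)xi + (R_xlen_t)X * (yi + (R_xlen_t)Y * zi)];
          }
      out[n] = v;
    }
  }
  return out;
}

static LogicalVector morph_pass(const LogicalVector& mask, int X, int Y, int Z, bool dilate) {
  LogicalVector out(clone(mask));
  const int* m = LOGICAL(mask);
  int* o = LOGICAL(out);
  const int off[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  R_xlen_t idx = 0;
  for (int k = 0; k < Z; ++k)
    for (int j = 0; j < Y; ++j)
      for (int i = 0; i < X; ++i, ++idx) {
        const bool cur = m[idx];
        if (dilate == cur) { o[idx] = cur; continue; }
        bool hit = false;
        for (int n = 0; n < 6; ++n) {
          const int x = i + off[n][0], y = j + off[n][1], z = k + off[n][2];
          // outside the grid counts as background
          bool nb = false;
          if (x >= 0 && y >= 0 && z >= 0 && x < X && y < Y && z < Z)
            nb = m[(R_xlen_t)x + (R_xlen_t)X * (y + (R_xlen_t)Y * z)];
          if (dilate ? nb : !nb) { hit = true; break; }
        }
        o[idx] = dilate ? (cur || hit) : (cur && !hit);
      }
  return out;
}

// [[Rcpp::export]]
LogicalVector cpp_dilate(LogicalVector mask, int iters) {
  int X, Y, Z; get_dims3(mask, X, Y, Z);
  LogicalVector cur = mask;
  for (int t = 0; t < iters; ++t) cur = morph_pass(cur, X, Y, Z, true);
  cur.attr("dim") = mask.attr("dim");
  return cur;
}

// [[Rcpp::export]]
LogicalVector cpp_erode(LogicalVector mask, int iters) {
  int X, Y, Z; get_dims3(mask, X, Y, Z);
  LogicalVector cur = mask;
  for (int t = 0; t < iters; ++t) cur = morph_pass(cur, X, Y, Z, false);
  cur.attr("dim") = mask.attr("dim");
  return cur;
}

// 6-connected component labelling; returns integer labels 1..L (0 background).
// [[Rcpp::export]]
IntegerVector cpp_label6(LogicalVector mask) {
  int X, Y, Z; get_dims3(mask, X, Y, Z);
  const R_xlen_t n = (R_xlen_t)X * Y * Z;
  IntegerVector lab(n);
  lab.attr("dim") = mask.attr("dim");
  const int* m = LOGICAL(mask);
  int* l = INTEGER(lab);
  std::vector<R_xlen_t> stack;
  int next = 0;
  const int off[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  for (R_xlen_t seed = 0; seed < n; ++seed) {
    if (!m[seed] || l[seed]) continue;
    ++next;
    l[seed] = next;
    stack.push_back(seed);
    while (!stack.empty()) {
      const R_xlen_t v = stack.back(); stack.pop_back();
      const int i = (int)(v % X), j = (int)((v / X) % Y), k = (int)(v / ((R_xlen_t)X * Y));
      for (int t = 0; t < 6; ++t) {
        const int x = i + off[t][0], y = j + off[t][1], z = k + off[t][2];
        if (x < 0 || y < 0 || z < 0 || x >= X || y >= Y || z >= Z) continue;
        const R_xlen_t w = (R_xlen_t)x + (R_xlen_t)X * (y + (R_xlen_t)Y * z);
        if (m[w] && !l[w]) { l[w] = next; stack.push_back(w); }
      }
    }
  }
  return lab;
}

static void gauss1d(std::vector<double>& buf, std::vector<double>& tmp,
                    const std::vector<double>& kern, int n, int stride, double* base) {
  const int r = (int)kern.size() / 2;
  for (int i = 0; i < n; ++i) buf[i] = base[(R_xlen_t)i * stride];
  for (int i = 0; i < n; ++i) {
    double acc = 0;
    for (int t = -r; t <= r; ++t) {
      int j = i + t;
      if (j < 0) j = -j - 1;           // reflect
      if (j >= n) j = 2 * n - 1 - j;
      acc += kern[t + r] * buf[j];
    }
    tmp[i] = acc;
  }
  for (int i = 0; i < n; ++i) base[(R_xlen_t)i * stride] = tmp[i];
}

// [[Rcpp::export]]
NumericVector cpp_gauss3d(NumericVector x, NumericVector sigma) {
  int X, Y, Z; get_dims3(x, X, Y, Z);
  NumericVector out = clone(x);
  double* p = REAL(out);
  const int dims[3] = {X, Y, Z};
  const R_xlen_t strides[3] = {1, X, (R_xlen_t)X * Y};
  for (int ax = 0; ax < 3; ++ax) {
    const double s = sigma[ax];
    if (s <= 0) continue;
    const int r = std::max(1, (int)std::ceil(3 * s));
    std::vector<double> kern(2 * r + 1);
    double ksum = 0;
    for (int t = -r; t <= r; ++t) { kern[t + r] = std::exp(-0.5 * t * t / (s * s)); ksum += kern[t + r]; }
    for (double& v : kern) v /= ksum;
    std::vector<double> buf(dims[ax]), tmp(dims[ax]);
    const int n = dims[ax];
    const R_xlen_t stride = strides[ax];
    // iterate over all lines along axis ax
    const int d1 = (ax == 0) ? Y : X;
    const int d2 = (ax == 2) ? Y : Z;
    const R_xlen_t s1 = (ax == 0) ? strides[1] : strides[0];
    const R_xlen_t s2 = (ax == 2) ? strides[1] : strides[2];
    for (int b = 0; b < d2; ++b)
      for (int a = 0; a < d1; ++a)
        gauss1d(buf, tmp, kern, n, (int)stride, p + a * s1 + b * s2);
  }
  return out;
}
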