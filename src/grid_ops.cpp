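// Voxel-grid kernels: connected components, boundary extraction, signed
// Euclidean distance transform, separable Gaussian smoothing, trilinear
// sampling. Grids are logical/numeric R arrays in column-major (x fastest)
// order with dimensions dim = (nx, ny, nz).
#include <Rcpp.h>
#include <queue>
#include <cmath>
#include <cstring>
#include <vector>
#include <limits>
using namespace Rcpp;

static inline R_xlen_t idx3(int x, int y, int z, int nx, int ny) {
  return (R_xlen_t)x + (R_xlen_t)nx * ((R_xlen_t)y + (R_xlen_t)ny * z);
}

// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector grid, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  IntegerVector lab(grid.size(), 0);
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (int z = 0; z < nz; ++z) for (int y = 0; y < ny; ++y) for (int x = 0; x < nx; ++x) {
    R_xlen_t i = idx3(x, y, z, nx, ny);
    if (!grid[i] || lab[i]) continue;
    ++next;
    lab[i] = next;
    stack.clear();
    stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t j = stack.back(); stack.pop_back();
      int zx = (int)(j / ((R_xlen_t)nx * ny));
      int rem = (int)(j - (R_xlen_t)zx * nx * ny);
      int zy = rem / nx, zz0 = rem % nx;
      for (int dz = -1; dz <= 1; ++dz) for (int dy = -1; dy <= 1; ++dy) for (int dx = -1; dx <= 1; ++dx) {
        if (!dx && !dy && !dz) continue;
        int X = zz0 + dx, Y = zy + dy, Z = zx + dz;
        if (X < 0 || Y < 0 || Z < 0 || X >= nx || Y >= ny || Z >= nz) continue;
        R_xlen_t k = idx3(X, Y, Z, nx, ny);
        if (grid[k] && !lab[k]) { lab[k] = next; stack.push_back(k); }
      }
    }
  }
  lab.attr("n") = next;
  return lab;
}

// Foreground voxels with at least one background 6-neighbour (faces count as
// background outside the array).
// [[Rcpp::export]]
LogicalVector cpp_boundary_voxels(LogicalVector grid, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  LogicalVector out(grid.size(), false);
  for (int z = 0; z < nz; ++z) for (int y = 0; y < ny; ++y) for (int x = 0; x < nx; ++x) {
    R_xlen_t i = idx3(x, y, z, nx, ny);
    if (!grid[i]) continue;
    bool b =
      (x == 0      || !grid[idx3(x-1,y,z,nx,ny)]) ||
      (x == nx - 1 || !grid[idx3(x+1,y,z,nx,ny)]) ||
      (y == 0      || !grid[idx3(x,y-1,z,nx,ny)]) ||
      (y == ny - 1 || !grid[idx3(x,y+1,z,nx,ny)]) ||
      (z == 0      || !grid[idx3(x,y,z-1,nx,ny)]) ||
      (z == nz - 1 || !grid[idx3(x,y,z+1,nx,ny)]);
    if (b) out[i] = true;
  }
  return out;
}

// 1D squared distance transform (Felzenszwalb & Huttenlocher) with grid
// step w along the axis.
static void dt1d(const double* f, double* d, int n, double w,
                 std::vector<int>& v, std::vector<double>& zbuf) {
  const double INF = std::numeric_limits<double>::infinity();
  const double w2 = w * w;
  int k = 0;
  v[0] = 0;
  zbuf[0] = -INF; zbuf[1] = INF;
  for (int q = 1; q < n; ++q) {
    if (f[q] == INF) continue;
    double s;
    while (true) {
      if (f[v[k]] == INF) { // first finite site
        if (k == 0) { v[0] = q; zbuf[0] = -INF; zbuf[1] = INF; goto placed; }
        --k;
        continue;
      }
      s = ((f[q] + w2 * q * q) - (f[v[k]] + w2 * v[k] * v[k])) / (2.0 * w2 * (q - v[k]));
      if (s <= zbuf[k]) { --k; continue; }
      break;
    }
    ++k;
    v[k] = q;
    zbuf[k] = s;
    zbuf[k + 1] = INF;
    placed: ;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zbuf[k + 1] < q) ++k;
    double dq = w * (q - v[k]);
    d[q] = (f[v[k]] == INF) ? INF : dq * dq + f[v[k]];
  }
}

static void edt_sq(std::vector<double>& g, int nx, int ny, int nz, const double* sp) {
  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), zbuf(nmax + 1);
  std::vector<int> v(nmax);
  // x pass
  for (int z = 0; z < nz; ++z) for (int y = 0; y < ny; ++y) {
    for (int x = 0; x < nx; ++x) f[x] = g[idx3(x,y,z,nx,ny)];
    dt1d(f.data(), d.data(), nx, sp[0], v, zbuf);
    for (int x = 0; x < nx; ++x) g[idx3(x,y,z,nx,ny)] = d[x];
  }
  // y pass
  for (int z = 0; z < nz; ++z) for (int x = 0; x < nx; ++x) {
    for (int y = 0; y < ny; ++y) f[y] = g[idx3(x,y,z,nx,ny)];
    dt1d(f.data(), d.data(), ny, sp[1], v, zbuf);
    for (int y = 0; y < ny; ++y) g[idx3(x,y,z,nx,ny)] = d[y];
  }
  // z pass
  for (int y = 0; y < ny; ++y) for (int x = 0; x < nx; ++x) {
    for (int z = 0; z < nz; ++z) f[z] = g[idx3(x,y,z,nx,ny)];
    dt1d(f.data(), d.data(), nz, sp[2], v, zbuf);
    for (int z = 0; z < nz; ++z) g[idx3(x,y,z,nx,ny)] = d[z];
  }
}

// Signed distance in mm: positive inside the foreground, negative outside.
// [[Rcpp::export]]
NumericVector cpp_signed_edt(LogicalVector grid, IntegerVector dim, NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double INF = std::numeric_limits<double>::infinity();
  R_xlen_t n = grid.size();
  std::vector<double> dout(n), din(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    dout[i] = grid[i] ? 0.0 : INF;  // distance to foreground
    din[i]  = grid[i] ? INF : 0.0;  // distance to background
  }
  double sp[3] = { spacing[0], spacing[1], spacing[2] };
  edt_sq(dout, nx, ny, nz, sp);
  edt_sq(din, nx, ny, nz, sp);
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = grid[i] ? std::sqrt(din[i]) : -std::sqrt(dout[i]);
  return out;
}

// Separable Gaussian smoothing, kernel radius 3*sigma (sigma in voxels per
// axis). mode 0: zero padding, mode 1: replicate edges.
// [[Rcpp::export]]
NumericVector cpp_gauss_blur(NumericVector field, IntegerVector dim,
                             NumericVector sigma_vox, int mode) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = field.size();
  std::vector<double> a(field.begin(), field.end()), b(n);
  const int dims[3] = { nx, ny, nz };
  for (int ax = 0; ax < 3; ++ax) {
    double s = sigma_vox[ax];
    if (s < 1e-6) continue;
    int r = (int)std::ceil(3.0 * s);
    std::vector<double> ker(2 * r + 1);
    double ksum = 0;
    for (int i = -r; i <= r; ++i) { ker[i + r] = std::exp(-0.5 * i * i / (s * s)); ksum += ker[i + r]; }
    for (auto& k : ker) k /= ksum;
    int len = dims[ax];
    R_xlen_t stride = (ax == 0) ? 1 : (ax == 1) ? (R_xlen_t)nx : (R_xlen_t)nx * ny;
    int on1 = (ax == 0) ? ny : nx;
    int on2 = (ax == 2) ? ny : nz;
    R_xlen_t os1 = (ax == 0) ? (R_xlen_t)nx : 1;
    R_xlen_t os2 = (ax == 2) ? (R_xlen_t)nx : (R_xlen_t)nx * ny;
    for (int j2 = 0; j2 < on2; ++j2) for (int j1 = 0; j1 < on1; ++j1) {
      R_xlen_t base = os1 * j1 + os2 * j2;
      for (int i = 0; i < len; ++i) {
        double acc = 0;
        for (int k = -r; k <= r; ++k) {
          int p = i + k;
          if (p < 0) { if (mode == 0) continue; p = 0; }
          if (p >= len) { if (mode == 0) continue; p = len - 1; }
          acc += ker[k + r] * a[base + stride * p];
        }
        b[base + stride * i] = acc;
      }
    }
    std::swap(a, b);
  }
  return NumericVector(a.begin(), a.end());
}

static inline double tri_sample(const double* f, int nx, int ny, int nz,
                                double x, double y, double z) {
  if (x < 0) x = 0; if (y < 0) y = 0; if (z < 0) z = 0;
  if (x > nx - 1) x = nx - 1; if (y > ny - 1) y = ny - 1; if (z > nz - 1) z = nz - 1;
  int x0 = (int)x, y0 = (int)y, z0 = (int)z;
  int x1 = std::min(x0 + 1, nx - 1), y1 = std::min(y0 + 1, ny - 1), z1 = std::min(z0 + 1, nz - 1);
  double fx = x - x0, fy = y - y0, fz = z - z0;
  double c000 = f[idx3(x0,y0,z0,nx,ny)], c100 = f[idx3(x1,y0,z0,nx,ny)];
  double c010 = f[idx3(x0,y1,z0,nx,ny)], c110 = f[idx3(x1,y1,z0,nx,ny)];
  double c001 = f[idx3(x0,y0,z1,nx,ny)], c101 = f[idx3(x1,y0,z1,nx,ny)];
  double c011 = f[idx3(x0,y1,z1,nx,ny)], c111 = f[idx3(x1,y1,z1,nx,ny)];
  double c00 = c000 * (1 - fx) + c100 * fx, c10 = c010 * (1 - fx) + c110 * fx;
  double c01 = c001 * (1 - fx) + c101 * fx, c11 = c011 * (1 - fx) + c111 * fx;
  double c0 = c00 * (1 - fy) + c10 * fy, c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

// Axis-aligned resampling: output voxel i along axis ax sits at source voxel
// coordinate start[ax] + i * step[ax] (0-based).
// [[Rcpp::export]]
NumericVector cpp_resample(NumericVector field, IntegerVector dim,
                           IntegerVector odim, NumericVector start, NumericVector step) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int ox = odim[0], oy = odim[1], oz = odim[2];
  NumericVector out((R_xlen_t)ox * oy * oz);
  const double* f = field.begin();
  R_xlen_t p = 0;
  for (int z = 0; z < oz; ++z) {
    double zc = start[2] + step[2] * z;
    for (int y = 0; y < oy; ++y) {
      double yc = start[1] + step[1] * y;
      for (int x = 0; x < ox; ++x, ++p)
        out[p] = tri_sample(f, nx, ny, nz, start[0] + step[0] * x, yc, zc);
    }
  }
  return out;
}

// Sampling at arbitrary voxel coordinates (rows of coords, 0-based).
// [[Rcpp::export]]
NumericVector cpp_interp(NumericVector field, IntegerVector dim, NumericMatrix coords) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double* f = field.begin();
  R_xlen_t n = coords.nrow();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = tri_sample(f, nx, ny, nz, coords(i, 0), coords(i, 1), coords(i, 2));
  return out;
}
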