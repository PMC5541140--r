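#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

static const double DINF = 1e30;

// 1-D squared-distance transform along a line with grid positions x_i = i*w
// (lower envelope of parabolas, Felzenszwalb & Huttenlocher).
static void dt1d(const double* f, double* d, int n, double w,
                 int* v, double* z) {
  int k = 0;
  v[0] = 0;
  z[0] = -DINF;
  z[1] = DINF;
  for (int q = 1; q < n; ++q) {
    double xq = q * w;
    double s;
    while (true) {
      int p = v[k];
      double xp = p * w;
      s = ((f[q] + xq * xq) - (f[p] + xp * xp)) / (2.0 * (xq - xp));
      if (s <= z[k] && k > 0) {
        --k;
      } else {
        break;
      }
    }
    if (s <= z[k]) {           // k == 0 and still dominated: replace
      v[0] = q;
    } else {
      ++k;
      v[k] = q;
      z[k] = s;
    }
    z[k + 1] = DINF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * w;
    while (z[k + 1] < xq) ++k;
    double dx = xq - v[k] * w;
    d[q] = dx * dx + f[v[k]];
  }
}

// Exact anisotropic Euclidean distance transform (mm) of a voxel mask.
// Distance is 0 on mask voxels; DINF-derived large values if mask empty.
// [[Rcpp::export]]
NumericVector cpp_edt3d(LogicalVector mask, IntegerVector dim,
                        NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = mask[i] ? 0.0 : DINF;

  const int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);
  double* po = REAL(out);

  // x (stride 1)
  for (int kz = 0; kz < nz; ++kz) {
    for (int jy = 0; jy < ny; ++jy) {
      R_xlen_t base = (R_xlen_t)nx * (jy + (R_xlen_t)ny * kz);
      dt1d(po + base, d.data(), nx, spacing[0], v.data(), z.data());
      std::copy(d.begin(), d.begin() + nx, po + base);
    }
  }
  // y (stride nx)
  for (int kz = 0; kz < nz; ++kz) {
    for (int ix = 0; ix < nx; ++ix) {
      R_xlen_t base = ix + (R_xlen_t)nx * ny * kz;
      for (int j = 0; j < ny; ++j) f[j] = po[base + (R_xlen_t)nx * j];
      dt1d(f.data(), d.data(), ny, spacing[1], v.data(), z.data());
      for (int j = 0; j < ny; ++j) po[base + (R_xlen_t)nx * j] = d[j];
    }
  }
  // z (stride nx*ny)
  const R_xlen_t sz = (R_xlen_t)nx * ny;
  for (int jy = 0; jy < ny; ++jy) {
    for (int ix = 0; ix < nx; ++ix) {
      R_xlen_t base = ix + (R_xlen_t)nx * jy;
      for (int kq = 0; kq < nz; ++kq) f[kq] = po[base + sz * kq];
      dt1d(f.data(), d.data(), nz, spacing[2], v.data(), z.data());
      for (int kq = 0; kq < nz; ++kq) po[base + sz * kq] = d[kq];
    }
  }
  for (R_xlen_t i = 0; i < n; ++i) po[i] = std::sqrt(po[i]);
  return out;
}

// Trilinear interpolation at continuous 0-based voxel coordinates,
// clamped to the grid boundary.
// [[Rcpp::export]]
NumericVector cpp_sample_trilinear(NumericVector vol, IntegerVector dim,
                                   NumericMatrix ijk) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t np = ijk.nrow();
  NumericVector out(np);
  const double* pv = REAL(vol);
  for (R_xlen_t p = 0; p < np; ++p) {
    double x = ijk(p, 0), y = ijk(p, 1), z = ijk(p, 2);
    if (x < 0) x = 0; if (x > nx - 1) x = nx - 1;
    if (y < 0) y = 0; if (y > ny - 1) y = ny - 1;
    if (z < 0) z = 0; if (z > nz - 1) z = nz - 1;
    int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
    if (x0 > nx - 2) x0 = nx - 2; if (x0 < 0) x0 = 0;
    if (y0 > ny - 2) y0 = ny - 2; if (y0 < 0) y0 = 0;
    if (z0 > nz - 2) z0 = nz - 2; if (z0 < 0) z0 = 0;
    int x1 = std::min(x0 + 1, nx - 1);
    int y1 = std::min(y0 + 1, ny - 1);
    int z1 = std::min(z0 + 1, nz - 1);
    double fx = x - x0, fy = y - y0, fz = z - z0;
    if (nx == 1) { x1 = 0; fx = 0; }
    if (ny == 1) { y1 = 0; fy = 0; }
    if (nz == 1) { z1 = 0; fz = 0; }
    #define V(i, j, k) pv[(R_xlen_t)(i) + (R_xlen_t)nx * ((j) + (R_xlen_t)ny * (k))]
    double c00 = V(x0, y0, z0) * (1 - fx) + V(x1, y0, z0) * fx;
    double c10 = V(x0, y1, z0) * (1 - fx) + V(x1, y1, z0) * fx;
    double c01 = V(x0, y0, z1) * (1 - fx) + V(x1, y0, z1) * fx;
    double c11 = V(x0, y1, z1) * (1 - fx) + V(x1, y1, z1) * fx;
    #undef V
    double c0 = c00 * (1 - fy) + c10 * fy;
    double c1 = c01 * (1 - fy) + c11 * fy;
    out[p] = c0 * (1 - fz) + c1 * fz;
  }
  return out;
}

// Nearest-voxel lookup (half-open voxel boundaries: voxel i owns
// [i-0.5, i+0.5)). Points outside the grid return `outside`.
// [[Rcpp::export]]
NumericVector cpp_sample_nearest(NumericVector vol, IntegerVector dim,
                                 NumericMatrix ijk, double outside) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t np = ijk.nrow();
  NumericVector out(np);
  const double* pv = REAL(vol);
  for (R_xlen_t p = 0; p < np; ++p) {
    int i = (int)std::floor(ijk(p, 0) + 0.5);
    int j = (int)std::floor(ijk(p, 1) + 0.5);
    int k = (int)std::floor(ijk(p, 2) + 0.5);
    if (i < 0 || i >= nx || j < 0 || j >= ny || k < 0 || k >= nz) {
      out[p] = outside;
    } else {
      out[p] = pv[(R_xlen_t)i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)];
    }
  }
  return out;
}

// Regional minima of a 3-D field under 26-connectivity, restricted to
// voxels with value < below. A plateau (connected equal-valued set) is a
// regional minimum iff no 26-neighbour of any plateau voxel has a smaller
// value. Returns the 1-based linear index of the representative (smallest
// linear index) of each qualifying plateau.
// [[Rcpp::export]]
IntegerVector cpp_regional_minima(NumericVector vol, IntegerVector dim,
                                  double below) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const double* pv = REAL(vol);
  std::vector<char> visited(n, 0);
  std::vector<R_xlen_t> reps;
  std::vector<R_xlen_t> plateau;

  for (R_xlen_t start = 0; start < n; ++start) {
    if (visited[start] || pv[start] >= below) continue;
    const double val = pv[start];
    bool isMin = true;
    plateau.clear();
    std::queue<R_xlen_t> q;
    q.push(start);
    visited[start] = 1;
    while (!q.empty()) {
      R_xlen_t cur = q.front();
      q.pop();
      plateau.push_back(cur);
      int cx = (int)(cur % nx);
      int cy = (int)((cur / nx) % ny);
      int cz = (int)(cur / ((R_xlen_t)nx * ny));
      for (int dz = -1; dz <= 1; ++dz) {
        for (int dy = -1; dy <= 1; ++dy) {
          for (int dx = -1; dx <= 1; ++dx) {
            if (dx == 0 && dy == 0 && dz == 0) continue;
            int mx = cx + dx, my = cy + dy, mz = cz + dz;
            if (mx < 0 || mx >= nx || my < 0 || my >= ny || mz < 0 || mz >= nz)
              continue;
            R_xlen_t nb = (R_xlen_t)mx + (R_xlen_t)nx * (my + (R_xlen_t)ny * mz);
            double nv = pv[nb];
            if (nv < val) {
              isMin = false;
            } else if (nv == val && !visited[nb]) {
              visited[nb] = 1;
              q.push(nb);
            }
          }
        }
      }
    }
    if (isMin) {
      R_xlen_t rep = plateau[0];
      for (size_t t = 1; t < plateau.size(); ++t)
        if (plateau[t] < rep) rep = plateau[t];
      reps.push_back(rep);
    }
  }
  std::sort(reps.begin(), reps.end());
  IntegerVector out(reps.size());
  for (size_t t = 0; t < reps.size(); ++t) out[t] = (int)(reps[t] + 1);
  return out;
}

static inline double pointSegDist2(double px, double py, double pz,
                                   double ax, double ay, double az,
                                   double bx, double by, double bz) {
  double abx = bx - ax, aby = by - ay, abz = bz - az;
  double apx = px - ax, apy = py - ay, apz = pz - az;
  double ab2 = abx * abx + aby * aby + abz * abz;
  double t = ab2 > 0 ? (apx * abx + apy * aby + apz * abz) / ab2 : 0.0;
  if (t < 0) t = 0;
  if (t > 1) t = 1;
  double dx = apx - t * abx, dy = apy - t * aby, dz = apz - t * abz;
  return dx * dx + dy * dy + dz * dz;
}

// Rasterize a tube of given radius around a polyline (world mm) into a
// voxel mask on an axis-aligned grid (world = origin + index * spacing).
// Returns maskIn with the tube voxels set TRUE.
// [[Rcpp::export]]
LogicalVector cpp_tube_mask(LogicalVector maskIn, IntegerVector dim,
                            NumericVector origin, NumericVector spacing,
                            NumericMatrix pts, double radius) {
  LogicalVector mask = clone(maskIn);
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double r2 = radius * radius;
  for (int s = 0; s + 1 < pts.nrow(); ++s) {
    double ax = pts(s, 0), ay = pts(s, 1), az = pts(s, 2);
    double bx = pts(s + 1, 0), by = pts(s + 1, 1), bz = pts(s + 1, 2);
    int i0 = (int)std::floor((std::min(ax, bx) - radius - origin[0]) / spacing[0]);
    int i1 = (int)std::ceil((std::max(ax, bx) + radius - origin[0]) / spacing[0]);
    int j0 = (int)std::floor((std::min(ay, by) - radius - origin[1]) / spacing[1]);
    int j1 = (int)std::ceil((std::max(ay, by) + radius - origin[1]) / spacing[1]);
    int k0 = (int)std::floor((std::min(az, bz) - radius - origin[2]) / spacing[2]);
    int k1 = (int)std::ceil((std::max(az, bz) + radius - origin[2]) / spacing[2]);
    i0 = std::max(i0, 0); i1 = std::min(i1, nx - 1);
    j0 = std::max(j0, 0); j1 = std::min(j1, ny - 1);
    k0 = std::max(k0, 0); k1 = std::min(k1, nz - 1);
    for (int k = k0; k <= k1; ++k) {
      double wz = origin[2] + k * spacing[2];
      for (int j = j0; j <= j1; ++j) {
        double wy = origin[1] + j * spacing[1];
        for (int i = i0; i <= i1; ++i) {
          double wx = origin[0] + i * spacing[0];
          if (pointSegDist2(wx, wy, wz, ax, ay, az, bx, by, bz) <= r2)
            mask[(R_xlen_t)i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)] = true;
        }
      }
    }
  }
  return mask;
}
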