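// 3D image kernels: separable Gaussian, Laplacian, exact anisotropic EDT,
// 26-connected labeling, plateau-aware local maxima, pyramid down/upsampling
// and small rasterizers for the synthetic scene generator.
//
// All arrays are R 3D arrays with dim = c(nz, ny, nx); the z index varies
// fastest in memory. Linear index (0-based): k + nz * (j + ny * i).

#include <Rcpp.h>
#include <vector>
#include <queue>
#include <array>
#include <cmath>
#include <limits>
#include <algorithm>

using namespace Rcpp;

static inline int lin(int k, int j, int i, int nz, int ny) {
  return k + nz * (j + ny * i);
}

// ---------------------------------------------------------------- filters --

// 1D convolution along one axis with clamped (replicate) boundaries.
static void conv_axis(std::vector<double>& src, std::vector<double>& dst,
                      int nz, int ny, int nx, int axis,
                      const std::vector<double>& ker) {
  int r = (int)(ker.size() - 1) / 2;
  int n[3] = {nz, ny, nx};
  int len = n[axis];
  for (int i = 0; i < nx; ++i) {
    for (int j = 0; j < ny; ++j) {
      for (int k = 0; k < nz; ++k) {
        int pos[3] = {k, j, i};
        double acc = 0.0;
        for (int t = -r; t <= r; ++t) {
          int q = pos[axis] + t;
          if (q < 0) q = 0;
          if (q >= len) q = len - 1;
          int p[3] = {pos[0], pos[1], pos[2]};
          p[axis] = q;
          acc += ker[t + r] * src[lin(p[0], p[1], p[2], nz, ny)];
        }
        dst[lin(k, j, i, nz, ny)] = acc;
      }
    }
  }
}

static std::vector<double> gauss_kernel(double sigma) {
  int r = std::max(1, (int)std::ceil(4.0 * sigma));
  std::vector<double> k(2 * r + 1);
  double s = 0.0;
  for (int t = -r; t <= r; ++t) {
    k[t + r] = std::exp(-0.5 * (double)t * t / (sigma * sigma));
    s += k[t + r];
  }
  for (double& v : k) v /= s;
  return k;
}

// [[Rcpp::export]]
NumericVector cpp_gaussian_blur(NumericVector img, IntegerVector dim,
                                NumericVector sigma_vox) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  std::vector<double> a(img.begin(), img.end());
  std::vector<double> b(a.size());
  for (int axis = 0; axis < 3; ++axis) {
    double s = sigma_vox[axis];
    if (s <= 1e-8) continue;
    std::vector<double> ker = gauss_kernel(s);
    conv_axis(a, b, nz, ny, nx, axis, ker);
    std::swap(a, b);
  }
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = dim;
  return out;
}

// 7-point Laplacian with physical spacing (µm), replicate boundaries.
// [[Rcpp::export]]
NumericVector cpp_laplacian(NumericVector img, IntegerVector dim,
                            NumericVector spacing) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  double wz = 1.0 / (spacing[0] * spacing[0]);
  double wy = 1.0 / (spacing[1] * spacing[1]);
  double wx = 1.0 / (spacing[2] * spacing[2]);
  NumericVector out(img.size());
  for (int i = 0; i < nx; ++i)
    for (int j = 0; j < ny; ++j)
      for (int k = 0; k < nz; ++k) {
        double c = img[lin(k, j, i, nz, ny)];
        double zm = img[lin(k > 0 ? k - 1 : 0, j, i, nz, ny)];
        double zp = img[lin(k < nz - 1 ? k + 1 : nz - 1, j, i, nz, ny)];
        double ym = img[lin(k, j > 0 ? j - 1 : 0, i, nz, ny)];
        double yp = img[lin(k, j < ny - 1 ? j + 1 : ny - 1, i, nz, ny)];
        double xm = img[lin(k, j, i > 0 ? i - 1 : 0, nz, ny)];
        double xp = img[lin(k, j, i < nx - 1 ? i + 1 : nx - 1, nz, ny)];
        out[lin(k, j, i, nz, ny)] =
          wz * (zm + zp - 2 * c) + wy * (ym + yp - 2 * c) + wx * (xm + xp - 2 * c);
      }
  out.attr("dim") = dim;
  return out;
}

// Mean-pool by integer factors f (per axis), replicate-padding the tail.
// [[Rcpp::export]]
NumericVector cpp_downsample3(NumericVector img, IntegerVector dim,
                              IntegerVector f) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  int fz = f[0], fy = f[1], fx = f[2];
  int mz = (nz + fz - 1) / fz, my = (ny + fy - 1) / fy, mx = (nx + fx - 1) / fx;
  NumericVector out(mz * (R_xlen_t)my * mx);
  for (int i = 0; i < mx; ++i)
    for (int j = 0; j < my; ++j)
      for (int k = 0; k < mz; ++k) {
        double acc = 0.0; int cnt = 0;
        for (int di = i * fx; di < std::min((i + 1) * fx, nx); ++di)
          for (int dj = j * fy; dj < std::min((j + 1) * fy, ny); ++dj)
            for (int dk = k * fz; dk < std::min((k + 1) * fz, nz); ++dk) {
              acc += img[lin(dk, dj, di, nz, ny)];
              ++cnt;
            }
        out[lin(k, j, i, mz, my)] = acc / cnt;
      }
  out.attr("dim") = IntegerVector::create(mz, my, mx);
  return out;
}

// Trilinear upsampling back to `dim` from a grid pooled by factors f.
// [[Rcpp::export]]
NumericVector cpp_upsample3(NumericVector src, IntegerVector sdim,
                            IntegerVector dim, IntegerVector f) {
  int mz = sdim[0], my = sdim[1], mx = sdim[2];
  int nz = dim[0], ny = dim[1], nx = dim[2];
  NumericVector out(nz * (R_xlen_t)ny * nx);
  for (int i = 0; i < nx; ++i) {
    double cx = (i - (f[2] - 1) * 0.5) / f[2];
    int ix = (int)std::floor(cx); double wx = cx - ix;
    int ix0 = std::min(std::max(ix, 0), mx - 1);
    int ix1 = std::min(ix0 + 1, mx - 1);
    if (ix < 0) wx = 0; if (ix >= mx - 1) wx = 0;
    for (int j = 0; j < ny; ++j) {
      double cy = (j - (f[1] - 1) * 0.5) / f[1];
      int iy = (int)std::floor(cy); double wy = cy - iy;
      int iy0 = std::min(std::max(iy, 0), my - 1);
      int iy1 = std::min(iy0 + 1, my - 1);
      if (iy < 0) wy = 0; if (iy >= my - 1) wy = 0;
      for (int k = 0; k < nz; ++k) {
        double cz = (k - (f[0] - 1) * 0.5) / f[0];
        int iz = (int)std::floor(cz); double wz = cz - iz;
        int iz0 = std::min(std::max(iz, 0), mz - 1);
        int iz1 = std::min(iz0 + 1, mz - 1);
        if (iz < 0) wz = 0; if (iz >= mz - 1) wz = 0;
        double v = 0.0;
        v += (1 - wz) * (1 - wy) * (1 - wx) * src[lin(iz0, iy0, ix0, mz, my)];
        v += wz * (1 - wy) * (1 - wx) * src[lin(iz1, iy0, ix0, mz, my)];
        v += (1 - wz) * wy * (1 - wx) * src[lin(iz0, iy1, ix0, mz, my)];
        v += wz * wy * (1 - wx) * src[lin(iz1, iy1, ix0, mz, my)];
        v += (1 - wz) * (1 - wy) * wx * src[lin(iz0, iy0, ix1, mz, my)];
        v += wz * (1 - wy) * wx * src[lin(iz1, iy0, ix1, mz, my)];
        v += (1 - wz) * wy * wx * src[lin(iz0, iy1, ix1, mz, my)];
        v += wz * wy * wx * src[lin(iz1, iy1, ix1, mz, my)];
        out[lin(k, j, i, nz, ny)] = v;
      }
    }
  }
  out.attr("dim") = dim;
  return out;
}

// ------------------------------------------------------------ local maxima --

// 26-connected local maxima of `resp` with value >= min_value.
// Plateaus (equal-valued connected sets with no strictly greater neighbor)
// contribute their smallest linear index. Returns 1-based linear indices.
// [[Rcpp::export]]
IntegerVector cpp_local_maxima(NumericVector resp, IntegerVector dim,
                               double min_value) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  R_xlen_t n = resp.size();
  std::vector<char> visited(n, 0);
  std::vector<int> keep;

  for (int i = 0; i < nx; ++i)
    for (int j = 0; j < ny; ++j)
      for (int k = 0; k < nz; ++k) {
        int p = lin(k, j, i, nz, ny);
        if (visited[p]) continue;
        double v = resp[p];
        if (!(v >= min_value)) continue;
        // flood the equal-valued plateau containing p
        std::vector<int> plateau;
        std::queue<std::array<int,3>> q;
        bool is_max = true;
        q.push({k, j, i});
        visited[p] = 1;
        while (!q.empty()) {
          std::array<int,3> c = q.front(); q.pop();
          int cp = lin(c[0], c[1], c[2], nz, ny);
          plateau.push_back(cp);
          for (int dz = -1; dz <= 1; ++dz)
            for (int dy = -1; dy <= 1; ++dy)
              for (int dx = -1; dx <= 1; ++dx) {
                if (!dz && !dy && !dx) continue;
                int zz = c[0] + dz, yy = c[1] + dy, xx = c[2] + dx;
                if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
                  continue;
                int np = lin(zz, yy, xx, nz, ny);
                double nv = resp[np];
                if (nv > v) { is_max = false; }
                else if (nv == v && !visited[np]) {
                  visited[np] = 1;
                  q.push({zz, yy, xx});
                }
              }
        }
        if (is_max) {
          int m = *std::min_element(plateau.begin(), plateau.end());
          keep.push_back(m + 1);
        }
      }
  std::sort(keep.begin(), keep.end());
  return IntegerVector(keep.begin(), keep.end());
}

// ------------------------------------------------------------------- EDT ---

// Felzenszwalb & Huttenlocher 1D squared distance transform on a sampled
// grid with spacing h. f/d have length n.
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n,
                 double h) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  const double INF = std::numeric_limits<double>::infinity();
  // f values use a large finite sentinel, never IEEE inf, so the
  // intersection s below is always finite and q cannot underrun.
  int q = 0;
  v[0] = 0;
  z[0] = -INF; z[1] = INF;
  for (int i = 1; i < n; ++i) {
    double xi = i * h;
    double s;
    while (true) {
      double xv = v[q] * h;
      s = ((f[i] + xi * xi) - (f[v[q]] + xv * xv)) / (2 * xi - 2 * xv);
      if (s <= z[q]) { --q; } else break;
    }
    ++q;
    v[q] = i;
    z[q] = s;
    z[q + 1] = INF;
  }
  q = 0;
  for (int i = 0; i < n; ++i) {
    double xi = i * h;
    while (z[q + 1] < xi) ++q;
    double xv = v[q] * h;
    d[i] = (xi - xv) * (xi - xv) + f[v[q]];
  }
}

// Exact Euclidean distance (µm) from every voxel center to the nearest
// target voxel center; anisotropic spacing. target: logical array.
// [[Rcpp::export]]
NumericVector cpp_edt(LogicalVector target, IntegerVector dim,
                      NumericVector spacing) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  const double BIG = 1e20;  // finite sentinel; see dt1d
  std::vector<double> d(target.size());
  for (R_xlen_t t = 0; t < target.size(); ++t)
    d[t] = target[t] ? 0.0 : BIG;

  std::vector<double> f(std::max(nz, std::max(ny, nx)));
  std::vector<double> o(std::max(nz, std::max(ny, nx)));

  // z axis
  for (int i = 0; i < nx; ++i)
    for (int j = 0; j < ny; ++j) {
      for (int k = 0; k < nz; ++k) f[k] = d[lin(k, j, i, nz, ny)];
      dt1d(f, o, nz, spacing[0]);
      for (int k = 0; k < nz; ++k) d[lin(k, j, i, nz, ny)] = o[k];
    }
  // y axis
  for (int i = 0; i < nx; ++i)
    for (int k = 0; k < nz; ++k) {
      for (int j = 0; j < ny; ++j) f[j] = d[lin(k, j, i, nz, ny)];
      dt1d(f, o, ny, spacing[1]);
      for (int j = 0; j < ny; ++j) d[lin(k, j, i, nz, ny)] = o[j];
    }
  // x axis
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) f[i] = d[lin(k, j, i, nz, ny)];
      dt1d(f, o, nx, spacing[2]);
      for (int i = 0; i < nx; ++i) d[lin(k, j, i, nz, ny)] = o[i];
    }

  NumericVector out(d.size());
  for (R_xlen_t t = 0; t < out.size(); ++t) out[t] = std::sqrt(d[t]);
  out.attr("dim") = dim;
  return out;
}

// ------------------------------------------------------------- labeling ----

// 26-connected component labeling; labels assigned in order of the smallest
// linear index of each component (deterministic).
// [[Rcpp::export]]
IntegerVector cpp_label26(LogicalVector mask, IntegerVector dim) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  IntegerVector lab(mask.size(), 0);
  int next = 0;
  std::queue<std::array<int,3>> q;
  for (int i = 0; i < nx; ++i)
    for (int j = 0; j < ny; ++j)
      for (int k = 0; k < nz; ++k) {
        int p = lin(k, j, i, nz, ny);
        if (!mask[p] || lab[p]) continue;
        ++next;
        lab[p] = next;
        q.push({k, j, i});
        while (!q.empty()) {
          std::array<int,3> c = q.front(); q.pop();
          for (int dz = -1; dz <= 1; ++dz)
            for (int dy = -1; dy <= 1; ++dy)
              for (int dx = -1; dx <= 1; ++dx) {
                if (!dz && !dy && !dx) continue;
                int zz = c[0] + dz, yy = c[1] + dy, xx = c[2] + dx;
                if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
                  continue;
                int np = lin(zz, yy, xx, nz, ny);
                if (mask[np] && !lab[np]) {
                  lab[np] = next;
                  q.push({zz, yy, xx});
                }
              }
        }
      }
  lab.attr("dim") = dim;
  return lab;
}

// ------------------------------------------------------------ rasterizers --

// Mark voxels within `radius` (µm) of the segment p0-p1 (physical z,y,x µm).
// mask is an integer array modified in place (0/1).
// [[Rcpp::export]]
void cpp_add_capsule(IntegerVector mask, IntegerVector dim,
                     NumericVector spacing, NumericVector p0,
                     NumericVector p1, double radius) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  double lo[3], hi[3];
  for (int a = 0; a < 3; ++a) {
    lo[a] = std::min(p0[a], p1[a]) - radius;
    hi[a] = std::max(p0[a], p1[a]) + radius;
  }
  int k0 = std::max(0, (int)std::floor(lo[0] / spacing[0] - 0.5));
  int k1 = std::min(nz - 1, (int)std::ceil(hi[0] / spacing[0] - 0.5));
  int j0 = std::max(0, (int)std::floor(lo[1] / spacing[1] - 0.5));
  int j1 = std::min(ny - 1, (int)std::ceil(hi[1] / spacing[1] - 0.5));
  int i0 = std::max(0, (int)std::floor(lo[2] / spacing[2] - 0.5));
  int i1 = std::min(nx - 1, (int)std::ceil(hi[2] / spacing[2] - 0.5));
  double e[3] = {p1[0] - p0[0], p1[1] - p0[1], p1[2] - p0[2]};
  double ee = e[0]*e[0] + e[1]*e[1] + e[2]*e[2];
  double r2 = radius * radius;
  for (int i = i0; i <= i1; ++i)
    for (int j = j0; j <= j1; ++j)
      for (int k = k0; k <= k1; ++k) {
        double c[3] = {(k + 0.5) * spacing[0], (j + 0.5) * spacing[1],
                       (i + 0.5) * spacing[2]};
        double w[3] = {c[0] - p0[0], c[1] - p0[1], c[2] - p0[2]};
        double t = ee > 0 ? (w[0]*e[0] + w[1]*e[1] + w[2]*e[2]) / ee : 0.0;
        if (t < 0) t = 0; if (t > 1) t = 1;
        double dz = w[0] - t * e[0], dy = w[1] - t * e[1], dx = w[2] - t * e[2];
        if (dz*dz + dy*dy + dx*dx <= r2)
          mask[lin(k, j, i, nz, ny)] = 1;
      }
}

// Add an anisotropic Gaussian blob (amplitude at the center) to img.
// [[Rcpp::export]]
void cpp_add_gaussian(NumericVector img, IntegerVector dim,
                      NumericVector spacing, NumericVector center,
                      NumericVector sigma, double amplitude) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  int k0 = std::max(0, (int)std::floor((center[0] - 4 * sigma[0]) / spacing[0] - 0.5));
  int k1 = std::min(nz - 1, (int)std::ceil((center[0] + 4 * sigma[0]) / spacing[0] - 0.5));
  int j0 = std::max(0, (int)std::floor((center[1] - 4 * sigma[1]) / spacing[1] - 0.5));
  int j1 = std::min(ny - 1, (int)std::ceil((center[1] + 4 * sigma[1]) / spacing[1] - 0.5));
  int i0 = std::max(0, (int)std::floor((center[2] - 4 * sigma[2]) / spacing[2] - 0.5));
  int i1 = std::min(nx - 1, (int)std::ceil((center[2] + 4 * sigma[2]) / spacing[2] - 0.5));
  for (int i = i0; i <= i1; ++i)
    for (int j = j0; j <= j1; ++j)
      for (int k = k0; k <= k1; ++k) {
        double dz = ((k + 0.5) * spacing[0] - center[0]) / sigma[0];
        double dy = ((j + 0.5) * spacing[1] - center[1]) / sigma[1];
        double dx = ((i + 0.5) * spacing[2] - center[2]) / sigma[2];
        img[lin(k, j, i, nz, ny)] +=
          amplitude * std::exp(-0.5 * (dz*dz + dy*dy + dx*dx));
      }
}

// Signed distance (µm) from each point to the union of capsules:
// min_j (dist(p, segment_j) - radius_j). Points and endpoints are (z,y,x) µm.
// [[Rcpp::export]]
NumericVector cpp_dist_to_capsules(NumericMatrix pts, NumericMatrix a,
                                   NumericMatrix b, NumericVector radius) {
  int n = pts.nrow(), m = a.nrow();
  NumericVector out(n);
  for (int p = 0; p < n; ++p) {
    double best = std::numeric_limits<double>::infinity();
    double pz = pts(p, 0), py = pts(p, 1), px = pts(p, 2);
    for (int s = 0; s < m; ++s) {
      double ez = b(s,0) - a(s,0), ey = b(s,1) - a(s,1), ex = b(s,2) - a(s,2);
      double wz = pz - a(s,0), wy = py - a(s,1), wx = px - a(s,2);
      double ee = ez*ez + ey*ey + ex*ex;
      double t = ee > 0 ? (wz*ez + wy*ey + wx*ex) / ee : 0.0;
      if (t < 0) t = 0; if (t > 1) t = 1;
      double dz = wz - t*ez, dy = wy - t*ey, dx = wx - t*ex;
      double d = std::sqrt(dz*dz + dy*dy + dx*dx) - radius[s];
      if (d < best) best = d;
    }
    out[p] = best;
  }
  return out;
}
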