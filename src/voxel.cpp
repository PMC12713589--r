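#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

// Voxel-grid operations: parity (ray-crossing) voxelization of watertight
// meshes, triangle-shell rasterization for the watertight wrap, 6-connected
// exterior flood fill, 3-4-5 chamfer distance transform and a 3x3x3 box
// filter. Grids use R's column-major layout: index = i + nx*(j + ny*k).

static inline int64_t gidx(int i, int j, int k, int nx, int ny) {
  return i + (int64_t)nx * (j + (int64_t)ny * k);
}

// [[Rcpp::export(name = ".cpp_voxelize_parity")]]
LogicalVector cpp_voxelize_parity(NumericMatrix V, IntegerMatrix F,
                                  NumericVector origin, double h,
                                  IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int m = F.nrow();
  LogicalVector out((int64_t)nx * ny * nz);
  // bucket triangles by (j,k) column bounding boxes
  std::vector<std::vector<int>> buckets((size_t)ny * nz);
  std::vector<double> ax(m), ay(m), az(m), e1x(m), e1y(m), e1z(m),
      e2x(m), e2y(m), e2z(m);
  for (int t = 0; t < m; ++t) {
    int a = F(t, 0) - 1, b = F(t, 1) - 1, c = F(t, 2) - 1;
    ax[t] = V(a, 0); ay[t] = V(a, 1); az[t] = V(a, 2);
    e1x[t] = V(b, 0) - ax[t]; e1y[t] = V(b, 1) - ay[t]; e1z[t] = V(b, 2) - az[t];
    e2x[t] = V(c, 0) - ax[t]; e2y[t] = V(c, 1) - ay[t]; e2z[t] = V(c, 2) - az[t];
    double ylo = std::min({V(a, 1), V(b, 1), V(c, 1)});
    double yhi = std::max({V(a, 1), V(b, 1), V(c, 1)});
    double zlo = std::min({V(a, 2), V(b, 2), V(c, 2)});
    double zhi = std::max({V(a, 2), V(b, 2), V(c, 2)});
    int jlo = std::max(0, (int)std::floor((ylo - origin[1]) / h) - 1);
    int jhi = std::min(ny - 1, (int)std::ceil((yhi - origin[1]) / h) + 1);
    int klo = std::max(0, (int)std::floor((zlo - origin[2]) / h) - 1);
    int khi = std::min(nz - 1, (int)std::ceil((zhi - origin[2]) / h) + 1);
    for (int k = klo; k <= khi; ++k)
      for (int j = jlo; j <= jhi; ++j)
        buckets[(size_t)j + (size_t)ny * k].push_back(t);
  }
  // small irrational offsets keep rays away from edges/vertices
  const double jit_y = 0.5 * h * 1.23456789e-4;
  const double jit_z = 0.5 * h * 0.98765432e-4;
  std::vector<double> ts;
  for (int k = 0; k < nz; ++k) {
    double rz = origin[2] + h * k + jit_z;
    for (int j = 0; j < ny; ++j) {
      double ry = origin[1] + h * j + jit_y;
      const std::vector<int> &bk = buckets[(size_t)j + (size_t)ny * k];
      if (bk.empty()) continue;
      ts.clear();
      for (int t : bk) {
        // Moeller-Trumbore with ray direction (1,0,0):
        // det = e1 . (dir x e2), dir x e2 = (0, -e2z, e2y)
        double det = e1z[t] * e2y[t] - e1y[t] * e2z[t];
        if (std::fabs(det) < 1e-14) continue;
        double inv = 1.0 / det;
        double tvy = ry - ay[t], tvz = rz - az[t];
        double u = (tvz * e2y[t] - tvy * e2z[t]) * inv;
        if (u < 0.0 || u > 1.0) continue;
        double v = (tvy * e1z[t] - tvz * e1y[t]) * inv;
        if (v < 0.0 || u + v > 1.0) continue;
        ts.push_back(ax[t] + u * e1x[t] + v * e2x[t]);
      }
      if (ts.size() < 2) continue;
      std::sort(ts.begin(), ts.end());
      // fill voxel centers between odd/even crossings
      for (size_t p = 0; p + 1 < ts.size(); p += 2) {
        int ilo = (int)std::ceil((ts[p] - origin[0]) / h);
        int ihi = (int)std::floor((ts[p + 1] - origin[0]) / h);
        if (ilo < 0) ilo = 0;
        if (ihi > nx - 1) ihi = nx - 1;
        for (int i = ilo; i <= ihi; ++i) out[gidx(i, j, k, nx, ny)] = true;
      }
    }
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_rasterize_shell")]]
LogicalVector cpp_rasterize_shell(NumericMatrix V, IntegerMatrix F,
                                  NumericVector origin, double h,
                                  IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  LogicalVector out((int64_t)nx * ny * nz);
  const int m = F.nrow();
  for (int t = 0; t < m; ++t) {
    int a = F(t, 0) - 1, b = F(t, 1) - 1, c = F(t, 2) - 1;
    double axp = V(a, 0), ayp = V(a, 1), azp = V(a, 2);
    double e1x = V(b, 0) - axp, e1y = V(b, 1) - ayp, e1z = V(b, 2) - azp;
    double e2x = V(c, 0) - axp, e2y = V(c, 1) - ayp, e2z = V(c, 2) - azp;
    double l1 = std::sqrt(e1x * e1x + e1y * e1y + e1z * e1z);
    double l2 = std::sqrt(e2x * e2x + e2y * e2y + e2z * e2z);
    double l3x = e2x - e1x, l3y = e2y - e1y, l3z = e2z - e1z;
    double l3 = std::sqrt(l3x * l3x + l3y * l3y + l3z * l3z);
    double lmax = std::max({l1, l2, l3});
    int n = std::max(1, (int)std::ceil(lmax / (0.5 * h)));
    for (int iu = 0; iu <= n; ++iu) {
      for (int iv = 0; iv <= n - iu; ++iv) {
        double u = (double)iu / n, v = (double)iv / n;
        double px = axp + u * e1x + v * e2x;
        double py = ayp + u * e1y + v * e2y;
        double pz = azp + u * e1z + v * e2z;
        int i = (int)std::floor((px - origin[0]) / h + 0.5);
        int j = (int)std::floor((py - origin[1]) / h + 0.5);
        int k = (int)std::floor((pz - origin[2]) / h + 0.5);
        if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) continue;
        out[gidx(i, j, k, nx, ny)] = true;
      }
    }
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_flood_exterior")]]
LogicalVector cpp_flood_exterior(LogicalVector occ, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int64_t n = (int64_t)nx * ny * nz;
  LogicalVector ext(n);
  std::vector<int64_t> stack;
  stack.reserve(1 << 16);
  auto push = [&](int i, int j, int k) {
    int64_t g = gidx(i, j, k, nx, ny);
    if (!occ[g] && !ext[g]) { ext[g] = true; stack.push_back(g); }
  };
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      push(0, j, k); push(nx - 1, j, k);
    }
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      push(i, 0, k); push(i, ny - 1, k);
    }
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      push(i, j, 0); push(i, j, nz - 1);
    }
  while (!stack.empty()) {
    int64_t g = stack.back();
    stack.pop_back();
    int i = (int)(g % nx);
    int j = (int)((g / nx) % ny);
    int k = (int)(g / ((int64_t)nx * ny));
    if (i > 0) push(i - 1, j, k);
    if (i < nx - 1) push(i + 1, j, k);
    if (j > 0) push(i, j - 1, k);
    if (j < ny - 1) push(i, j + 1, k);
    if (k > 0) push(i, j, k - 1);
    if (k < nz - 1) push(i, j, k + 1);
  }
  return ext;
}

// [[Rcpp::export(name = ".cpp_chamfer_dt")]]
IntegerVector cpp_chamfer_dt(LogicalVector occ, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int64_t n = (int64_t)nx * ny * nz;
  const int INF = INT_MAX / 4;
  IntegerVector d(n);
  for (int64_t g = 0; g < n; ++g) d[g] = occ[g] ? INF : 0;
  // 3-4-5 chamfer weights for face/edge/corner moves, forward then backward
  auto relax = [&](int64_t g, int i, int j, int k, int di, int dj, int dk) {
    int ii = i + di, jj = j + dj, kk = k + dk;
    if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) return;
    int w = 3 + (std::abs(di) + std::abs(dj) + std::abs(dk) - 1);
    // manhattan 1 -> 3, 2 -> 4, 3 -> 5
    int cand = d[gidx(ii, jj, kk, nx, ny)];
    if (cand < INF && cand + w < d[g]) d[g] = cand + w;
  };
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int64_t g = gidx(i, j, k, nx, ny);
        if (d[g] == 0) continue;
        for (int dk = -1; dk <= 0; ++dk)
          for (int dj = -1; dj <= 1; ++dj)
            for (int di = -1; di <= 1; ++di) {
              if (dk == 0 && (dj > 0 || (dj == 0 && di >= 0))) continue;
              relax(g, i, j, k, di, dj, dk);
            }
      }
  for (int k = nz - 1; k >= 0; --k)
    for (int j = ny - 1; j >= 0; --j)
      for (int i = nx - 1; i >= 0; --i) {
        int64_t g = gidx(i, j, k, nx, ny);
        if (d[g] == 0) continue;
        for (int dk = 0; dk <= 1; ++dk)
          for (int dj = -1; dj <= 1; ++dj)
            for (int di = -1; di <= 1; ++di) {
              if (dk == 0 && (dj < 0 || (dj == 0 && di <= 0))) continue;
              relax(g, i, j, k, di, dj, dk);
            }
      }
  return d;
}

// [[Rcpp::export(name = ".cpp_box_smooth3")]]
NumericVector cpp_box_smooth3(NumericVector f, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector out((int64_t)nx * ny * nz);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        double s = 0.0;
        int cnt = 0;
        for (int dk = -1; dk <= 1; ++dk) {
          int kk = k + dk;
          if (kk < 0 || kk >= nz) continue;
          for (int dj = -1; dj <= 1; ++dj) {
            int jj = j + dj;
            if (jj < 0 || jj >= ny) continue;
            for (int di = -1; di <= 1; ++di) {
              int ii = i + di;
              if (ii < 0 || ii >= nx) continue;
              s += f[gidx(ii, jj, kk, nx, ny)];
              ++cnt;
            }
          }
        }
        out[gidx(i, j, k, nx, ny)] = s / cnt;
      }
  return out;
}
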