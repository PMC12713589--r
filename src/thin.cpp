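#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

// Topology-preserving sequential 3D thinning. A voxel may be deleted iff it
// is simple in the sense of Malandain & Bertrand: exactly one 26-connected
// object component in its 26-neighbourhood and exactly one 6-connected
// background component in its 18-neighbourhood touching a face neighbour.
// Curve endpoints (exactly one object 26-neighbour) and isolated voxels are
// preserved, which yields a 1-voxel-wide centerline. Deletion is ordered by
// a 3-4-5 chamfer distance transform so the skeleton stays medial.

static inline int64_t gidx(int i, int j, int k, int nx, int ny) {
  return i + (int64_t)nx * (j + (int64_t)ny * k);
}

namespace {

struct Vol {
  const int nx, ny, nz;
  std::vector<uint8_t> occ;
  Vol(int nx_, int ny_, int nz_) : nx(nx_), ny(ny_), nz(nz_),
    occ((size_t)nx_ * ny_ * nz_, 0) {}
  inline bool get(int i, int j, int k) const {
    if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) return false;
    return occ[gidx(i, j, k, nx, ny)] != 0;
  }
};

// number of object 26-neighbours
int n26(const Vol &v, int i, int j, int k) {
  int c = 0;
  for (int dk = -1; dk <= 1; ++dk)
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di) {
        if (!di && !dj && !dk) continue;
        if (v.get(i + di, j + dj, k + dk)) ++c;
      }
  return c;
}

// local 3x3x3 cube index (0..26), center = 13
inline int lidx(int di, int dj, int dk) {
  return (di + 1) + 3 * (dj + 1) + 9 * (dk + 1);
}

bool is_simple(const Vol &v, int i, int j, int k) {
  bool obj[27];
  for (int dk = -1; dk <= 1; ++dk)
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di)
        obj[lidx(di, dj, dk)] = v.get(i + di, j + dj, k + dk);

  // --- C*: 26-components of the object within N26 (center removed) ---
  int comp = 0;
  bool seen[27] = {false};
  seen[13] = true;
  int stack[27];
  for (int s = 0; s < 27; ++s) {
    if (s == 13 || seen[s] || !obj[s]) continue;
    ++comp;
    if (comp > 1) return false;
    int top = 0;
    stack[top++] = s;
    seen[s] = true;
    while (top > 0) {
      int cur = stack[--top];
      int ci = cur % 3 - 1, cj = (cur / 3) % 3 - 1, ck = cur / 9 - 1;
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            int ni = ci + di, nj = cj + dj, nk = ck + dk;
            if (ni < -1 || nj < -1 || nk < -1 || ni > 1 || nj > 1 || nk > 1)
              continue;
            int l = lidx(ni, nj, nk);
            if (l == 13 || seen[l] || !obj[l]) continue;
            seen[l] = true;
            stack[top++] = l;
          }
    }
  }
  if (comp != 1) return false;

  // --- Cbar: 6-components of background within N18, seeded at face
  //     neighbours (those are 6-adjacent to the center) ---
  auto in18 = [](int di, int dj, int dk) {
    int man = std::abs(di) + std::abs(dj) + std::abs(dk);
    return man >= 1 && man <= 2;
  };
  bool bseen[27] = {false};
  int bcomp = 0;
  const int fdi[6] = {1, -1, 0, 0, 0, 0};
  const int fdj[6] = {0, 0, 1, -1, 0, 0};
  const int fdk[6] = {0, 0, 0, 0, 1, -1};
  for (int f = 0; f < 6; ++f) {
    int l0 = lidx(fdi[f], fdj[f], fdk[f]);
    if (obj[l0] || bseen[l0]) continue;
    ++bcomp;
    if (bcomp > 1) return false;
    int top = 0;
    stack[top++] = l0;
    bseen[l0] = true;
    while (top > 0) {
      int cur = stack[--top];
      int ci = cur % 3 - 1, cj = (cur / 3) % 3 - 1, ck = cur / 9 - 1;
      const int ddi[6] = {1, -1, 0, 0, 0, 0};
      const int ddj[6] = {0, 0, 1, -1, 0, 0};
      const int ddk[6] = {0, 0, 0, 0, 1, -1};
      for (int q = 0; q < 6; ++q) {
        int ni = ci + ddi[q], nj = cj + ddj[q], nk = ck + ddk[q];
        if (ni < -1 || nj < -1 || nk < -1 || ni > 1 || nj > 1 || nk > 1)
          continue;
        if (!in18(ni, nj, nk)) continue;
        int l = lidx(ni, nj, nk);
        if (bseen[l] || obj[l]) continue;
        bseen[l] = true;
        stack[top++] = l;
      }
    }
  }
  return bcomp == 1;
}

} // namespace

// [[Rcpp::export(name = ".cpp_thin_volume")]]
LogicalVector cpp_thin_volume(LogicalVector occ, IntegerVector dims,
                              IntegerVector chamfer) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  Vol v(nx, ny, nz);
  const int64_t n = (int64_t)nx * ny * nz;
  for (int64_t g = 0; g < n; ++g) v.occ[g] = occ[g] ? 1 : 0;

  // Six directional subiterations per pass (erode from each face of the
  // object in turn) keep the erosion symmetric; a purely sequential
  // deletion order would eat one side first and leave off-axis spurs.
  struct Cand { int d; int64_t g; };
  const int fdi[6] = {1, -1, 0, 0, 0, 0};
  const int fdj[6] = {0, 0, 1, -1, 0, 0};
  const int fdk[6] = {0, 0, 0, 0, 1, -1};
  bool changed = true;
  std::vector<Cand> cands;
  while (changed) {
    changed = false;
    for (int dir = 0; dir < 6; ++dir) {
      cands.clear();
      for (int k = 0; k < nz; ++k)
        for (int j = 0; j < ny; ++j)
          for (int i = 0; i < nx; ++i) {
            int64_t g = gidx(i, j, k, nx, ny);
            if (!v.occ[g]) continue;
            // border in this direction only
            if (v.get(i + fdi[dir], j + fdj[dir], k + fdk[dir])) continue;
            cands.push_back({chamfer[g], g});
          }
      std::stable_sort(cands.begin(), cands.end(),
                       [](const Cand &a, const Cand &b) {
                         return a.d < b.d || (a.d == b.d && a.g < b.g);
                       });
      for (const Cand &c : cands) {
        int64_t g = c.g;
        if (!v.occ[g]) continue;
        int i = (int)(g % nx);
        int j = (int)((g / nx) % ny);
        int k = (int)(g / ((int64_t)nx * ny));
        if (v.get(i + fdi[dir], j + fdj[dir], k + fdk[dir])) continue;
        int nb = n26(v, i, j, k);
        if (nb <= 1) continue;          // endpoint or isolated: preserve
        if (!is_simple(v, i, j, k)) continue;
        v.occ[g] = 0;
        changed = true;
      }
    }
  }
  LogicalVector out(n);
  for (int64_t g = 0; g < n; ++g) out[g] = v.occ[g] != 0;
  return out;
}
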