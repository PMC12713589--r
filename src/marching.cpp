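#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Marching tetrahedra over a scalar field sampled on a regular grid.
// Each grid cube is split into six tetrahedra sharing the main diagonal
// (corner 0 -> corner 6); the split is identical in every cube, so cube-face
// diagonals agree between neighbouring cubes and the extracted surface is
// watertight by construction. Surface vertices live on grid edges and are
// deduplicated through a canonical (lo,hi) grid-index key, so shared edges
// yield bitwise-identical vertices.

static const int TETS[6][4] = {
  {0, 5, 1, 6}, {0, 1, 2, 6}, {0, 2, 3, 6},
  {0, 3, 7, 6}, {0, 7, 4, 6}, {0, 4, 5, 6}
};

struct MTState {
  std::unordered_map<uint64_t, int> edge_vertex;
  std::vector<double> vx, vy, vz;
  std::vector<int> tri;
  const double *field;
  double level, h;
  double ox, oy, oz;
  int nx, ny, nz;

  inline void coords(int64_t g, double &x, double &y, double &z) const {
    int i = (int)(g % nx);
    int j = (int)((g / nx) % ny);
    int k = (int)(g / ((int64_t)nx * ny));
    x = ox + h * i; y = oy + h * j; z = oz + h * k;
  }

  int edge_id(int64_t a, int64_t b) {
    if (a > b) std::swap(a, b);
    // grid has far fewer than 2^32 nodes and b - a is bounded by one cube
    // diagonal stride, so (a, b - a) packs exactly into 64 bits
    uint64_t key = ((uint64_t)a << 32) | (uint64_t)(b - a);
    auto it = edge_vertex.find(key);
    if (it != edge_vertex.end()) return it->second;
    double fa = field[a], fb = field[b];
    double t = (level - fa) / (fb - fa);
    if (t < 0.0) t = 0.0;
    if (t > 1.0) t = 1.0;
    double ax, ay, az, bx, by, bz;
    coords(a, ax, ay, az);
    coords(b, bx, by, bz);
    vx.push_back(ax + t * (bx - ax));
    vy.push_back(ay + t * (by - ay));
    vz.push_back(az + t * (bz - az));
    int id = (int)vx.size() - 1;
    edge_vertex.emplace(key, id);
    return id;
  }

  void emit(int v0, int v1, int v2,
            double inx, double iny, double inz,
            double outx, double outy, double outz) {
    // orient so the normal points from the inside region toward the outside
    double ax = vx[v1] - vx[v0], ay = vy[v1] - vy[v0], az = vz[v1] - vz[v0];
    double bx = vx[v2] - vx[v0], by = vy[v2] - vy[v0], bz = vz[v2] - vz[v0];
    double nxv = ay * bz - az * by;
    double nyv = az * bx - ax * bz;
    double nzv = ax * by - ay * bx;
    double rx = outx - inx, ry = outy - iny, rz = outz - inz;
    if (nxv * rx + nyv * ry + nzv * rz < 0.0) std::swap(v1, v2);
    tri.push_back(v0); tri.push_back(v1); tri.push_back(v2);
  }
};

// [[Rcpp::export(name = ".cpp_marching_tetrahedra")]]
List cpp_marching_tetrahedra(NumericVector field, IntegerVector dims,
                             NumericVector origin, double h, double level) {
  MTState st;
  st.field = field.begin();
  st.level = level; st.h = h;
  st.ox = origin[0]; st.oy = origin[1]; st.oz = origin[2];
  st.nx = dims[0]; st.ny = dims[1]; st.nz = dims[2];
  const int nx = st.nx, ny = st.ny, nz = st.nz;
  const int64_t sx = 1, sy = nx, sz = (int64_t)nx * ny;

  const int64_t off[8] = {0, sx, sx + sy, sy, sz, sx + sz, sx + sy + sz, sy + sz};

  for (int k = 0; k < nz - 1; ++k) {
    for (int j = 0; j < ny - 1; ++j) {
      int64_t base0 = sy * j + sz * k;
      for (int i = 0; i < nx - 1; ++i) {
        int64_t base = base0 + i;
        // quick reject: all corners on one side
        bool any_in = false, any_out = false;
        double cf[8];
        for (int c = 0; c < 8; ++c) {
          cf[c] = st.field[base + off[c]];
          if (cf[c] < level) any_in = true; else any_out = true;
        }
        if (!any_in || !any_out) continue;
        for (int t = 0; t < 6; ++t) {
          int64_t g[4];
          double f[4];
          bool in[4];
          int n_in = 0;
          for (int c = 0; c < 4; ++c) {
            int corner = TETS[t][c];
            g[c] = base + off[corner];
            f[c] = cf[corner];
            in[c] = f[c] < level;
            if (in[c]) ++n_in;
          }
          if (n_in == 0 || n_in == 4) continue;
          // centroids of inside / outside corners for orientation
          double cix = 0, ciy = 0, ciz = 0, cox = 0, coy = 0, coz = 0;
          int ni = 0, no = 0;
          for (int c = 0; c < 4; ++c) {
            double x, y, z;
            st.coords(g[c], x, y, z);
            if (in[c]) { cix += x; ciy += y; ciz += z; ++ni; }
            else { cox += x; coy += y; coz += z; ++no; }
          }
          cix /= ni; ciy /= ni; ciz /= ni;
          cox /= no; coy /= no; coz /= no;

          int idx_in[4], idx_out[4];
          int a = 0, b = 0;
          for (int c = 0; c < 4; ++c) {
            if (in[c]) idx_in[a++] = c; else idx_out[b++] = c;
          }
          if (n_in == 1) {
            int A = idx_in[0];
            int e0 = st.edge_id(g[A], g[idx_out[0]]);
            int e1 = st.edge_id(g[A], g[idx_out[1]]);
            int e2 = st.edge_id(g[A], g[idx_out[2]]);
            st.emit(e0, e1, e2, cix, ciy, ciz, cox, coy, coz);
          } else if (n_in == 3) {
            int A = idx_out[0];
            int e0 = st.edge_id(g[A], g[idx_in[0]]);
            int e1 = st.edge_id(g[A], g[idx_in[1]]);
            int e2 = st.edge_id(g[A], g[idx_in[2]]);
            st.emit(e0, e1, e2, cix, ciy, ciz, cox, coy, coz);
          } else {
            int A = idx_in[0], B = idx_in[1], C = idx_out[0], D = idx_out[1];
            int eAC = st.edge_id(g[A], g[C]);
            int eAD = st.edge_id(g[A], g[D]);
            int eBC = st.edge_id(g[B], g[C]);
            int eBD = st.edge_id(g[B], g[D]);
            st.emit(eAC, eAD, eBD, cix, ciy, ciz, cox, coy, coz);
            st.emit(eAC, eBD, eBC, cix, ciy, ciz, cox, coy, coz);
          }
        }
      }
    }
  }

  int nv = (int)st.vx.size();
  NumericMatrix Vm(nv, 3);
  for (int i = 0; i < nv; ++i) {
    Vm(i, 0) = st.vx[i]; Vm(i, 1) = st.vy[i]; Vm(i, 2) = st.vz[i];
  }
  int nf = (int)st.tri.size() / 3;
  IntegerMatrix Fm(nf, 3);
  for (int i = 0; i < nf; ++i) {
    Fm(i, 0) = st.tri[3 * i] + 1;
    Fm(i, 1) = st.tri[3 * i + 1] + 1;
    Fm(i, 2) = st.tri[3 * i + 2] + 1;
  }
  return List::create(_["vertices"] = Vm, _["faces"] = Fm);
}
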