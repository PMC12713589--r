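#include <Rcpp.h>
#include <vector>
#include <queue>
#include <set>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Quadric edge-collapse mesh simplification (Garland-Heckbert error
// quadrics). Candidate collapses live in a lazy min-heap keyed by quadric
// cost; a collapse is rejected if it breaks the link condition, creates a
// degenerate face or flips a face normal.

namespace {

struct Quadric {
  // symmetric 4x4: a11..a14, a22..a24, a33, a34, a44
  double q[10];
  Quadric() { std::fill(q, q + 10, 0.0); }
  void add_plane(double a, double b, double c, double d, double w) {
    double p[4] = {a, b, c, d};
    int t = 0;
    for (int i = 0; i < 4; ++i)
      for (int j = i; j < 4; ++j) q[t++] += w * p[i] * p[j];
  }
  Quadric &operator+=(const Quadric &o) {
    for (int i = 0; i < 10; ++i) q[i] += o.q[i];
    return *this;
  }
  double eval(double x, double y, double z) const {
    // v' Q v with v = (x,y,z,1)
    return q[0]*x*x + 2*q[1]*x*y + 2*q[2]*x*z + 2*q[3]*x
         + q[4]*y*y + 2*q[5]*y*z + 2*q[6]*y
         + q[7]*z*z + 2*q[8]*z
         + q[9];
  }
  bool optimal(double &x, double &y, double &z) const {
    // solve [A b; 0 1] v = (0,0,0,1) -> A p = -b
    double A[3][3] = {{q[0], q[1], q[2]}, {q[1], q[4], q[5]}, {q[2], q[5], q[7]}};
    double b[3] = {-q[3], -q[6], -q[8]};
    // Gaussian elimination with partial pivoting
    int piv[3] = {0, 1, 2};
    double M[3][4];
    for (int i = 0; i < 3; ++i) {
      for (int j = 0; j < 3; ++j) M[i][j] = A[i][j];
      M[i][3] = b[i];
    }
    (void)piv;
    for (int c = 0; c < 3; ++c) {
      int best = c;
      for (int r = c + 1; r < 3; ++r)
        if (std::fabs(M[r][c]) > std::fabs(M[best][c])) best = r;
      if (std::fabs(M[best][c]) < 1e-10) return false;
      std::swap(M[c], M[best]);
      for (int r = 0; r < 3; ++r) {
        if (r == c) continue;
        double f = M[r][c] / M[c][c];
        for (int j = c; j < 4; ++j) M[r][j] -= f * M[c][j];
      }
    }
    x = M[0][3] / M[0][0];
    y = M[1][3] / M[1][1];
    z = M[2][3] / M[2][2];
    return std::isfinite(x) && std::isfinite(y) && std::isfinite(z);
  }
};

struct Cand {
  double cost;
  int u, v;
  long stamp;
  double px, py, pz;
  bool operator<(const Cand &o) const { return cost > o.cost; } // min-heap
};

} // namespace

// [[Rcpp::export(name = ".cpp_decimate_qec")]]
List cpp_decimate_qec(NumericMatrix Vm, IntegerMatrix Fm, int target) {
  const int n0 = Vm.nrow(), m0 = Fm.nrow();
  std::vector<double> VX(n0), VY(n0), VZ(n0);
  for (int i = 0; i < n0; ++i) { VX[i] = Vm(i,0); VY[i] = Vm(i,1); VZ[i] = Vm(i,2); }
  std::vector<std::array<int,3>> F(m0);
  std::vector<bool> face_alive(m0, true), vert_alive(n0, true);
  for (int f = 0; f < m0; ++f) F[f] = {Fm(f,0)-1, Fm(f,1)-1, Fm(f,2)-1};

  std::vector<std::vector<int>> vfaces(n0);
  for (int f = 0; f < m0; ++f)
    for (int c = 0; c < 3; ++c) vfaces[F[f][c]].push_back(f);

  std::vector<Quadric> Q(n0);
  auto face_normal = [&](int f, double &nx, double &ny, double &nz,
                         double &area2) {
    int a = F[f][0], b = F[f][1], c = F[f][2];
    double ux = VX[b]-VX[a], uy = VY[b]-VY[a], uz = VZ[b]-VZ[a];
    double vx = VX[c]-VX[a], vy = VY[c]-VY[a], vz = VZ[c]-VZ[a];
    nx = uy*vz - uz*vy; ny = uz*vx - ux*vz; nz = ux*vy - uy*vx;
    area2 = std::sqrt(nx*nx + ny*ny + nz*nz);
  };
  for (int f = 0; f < m0; ++f) {
    double nx, ny, nz, a2;
    face_normal(f, nx, ny, nz, a2);
    if (a2 < 1e-300) continue;
    double inv = 1.0 / a2;
    nx *= inv; ny *= inv; nz *= inv;
    int a = F[f][0];
    double d = -(nx*VX[a] + ny*VY[a] + nz*VZ[a]);
    for (int c = 0; c < 3; ++c) Q[F[f][c]].add_plane(nx, ny, nz, d, 0.5*a2);
  }

  std::vector<long> version(n0, 0);
  std::priority_queue<Cand> heap;

  auto neighbors = [&](int u) {
    std::set<int> s;
    for (int f : vfaces[u]) {
      if (!face_alive[f]) continue;
      for (int c = 0; c < 3; ++c) if (F[f][c] != u) s.insert(F[f][c]);
    }
    return s;
  };

  auto push_edge = [&](int u, int v) {
    if (u > v) std::swap(u, v);
    Quadric q = Q[u];
    q += Q[v];
    double x, y, z;
    double bx = 0.5*(VX[u]+VX[v]), by = 0.5*(VY[u]+VY[v]), bz = 0.5*(VZ[u]+VZ[v]);
    if (!q.optimal(x, y, z)) { x = bx; y = by; z = bz; }
    double c_opt = q.eval(x, y, z);
    double c_mid = q.eval(bx, by, bz);
    double c_u = q.eval(VX[u], VY[u], VZ[u]);
    double c_v = q.eval(VX[v], VY[v], VZ[v]);
    double best = c_opt; double px = x, py = y, pz = z;
    if (c_mid < best) { best = c_mid; px = bx; py = by; pz = bz; }
    if (c_u < best) { best = c_u; px = VX[u]; py = VY[u]; pz = VZ[u]; }
    if (c_v < best) { best = c_v; px = VX[v]; py = VY[v]; pz = VZ[v]; }
    heap.push({best, u, v, version[u] + version[v], px, py, pz});
  };

  {
    std::set<std::pair<int,int>> edges;
    for (int f = 0; f < m0; ++f)
      for (int c = 0; c < 3; ++c) {
        int a = F[f][c], b = F[f][(c+1)%3];
        if (a > b) std::swap(a, b);
        edges.insert({a, b});
      }
    for (auto &e : edges) push_edge(e.first, e.second);
  }

  int alive = n0;
  while (alive > target && !heap.empty()) {
    Cand c = heap.top();
    heap.pop();
    int u = c.u, v = c.v;
    if (!vert_alive[u] || !vert_alive[v]) continue;
    if (c.stamp != version[u] + version[v]) continue;

    // link condition: common neighbours must be exactly the opposite
    // vertices of faces sharing edge (u,v)
    std::set<int> nu = neighbors(u), nv = neighbors(v);
    if (!nu.count(v)) continue; // edge no longer exists
    std::vector<int> common;
    std::set_intersection(nu.begin(), nu.end(), nv.begin(), nv.end(),
                          std::back_inserter(common));
    std::set<int> opp;
    for (int f : vfaces[u]) {
      if (!face_alive[f]) continue;
      bool hasv = false;
      for (int cc = 0; cc < 3; ++cc) if (F[f][cc] == v) hasv = true;
      if (!hasv) continue;
      for (int cc = 0; cc < 3; ++cc)
        if (F[f][cc] != u && F[f][cc] != v) opp.insert(F[f][cc]);
    }
    if (common.size() != opp.size()) continue;
    bool linkok = true;
    for (int w : common) if (!opp.count(w)) { linkok = false; break; }
    if (!linkok) continue;

    // simulate: check for flips/degeneracies among surviving faces
    double ox = VX[u], oy = VY[u], oz = VZ[u];
    double ovx = VX[v], ovy = VY[v], ovz = VZ[v];
    bool ok = true;
    for (int pass = 0; pass < 2 && ok; ++pass) {
      int w0 = pass == 0 ? u : v;
      for (int f : vfaces[w0]) {
        if (!face_alive[f]) continue;
        bool killed = false;
        int idsz[3];
        for (int cc = 0; cc < 3; ++cc) {
          int vv = F[f][cc];
          idsz[cc] = vv;
        }
        bool hasu = idsz[0]==u||idsz[1]==u||idsz[2]==u;
        bool hasv2 = idsz[0]==v||idsz[1]==v||idsz[2]==v;
        if (hasu && hasv2) killed = true;
        if (killed) continue;
        double nx0, ny0, nz0, a20;
        face_normal(f, nx0, ny0, nz0, a20);
        // move
        VX[u] = c.px; VY[u] = c.py; VZ[u] = c.pz;
        VX[v] = c.px; VY[v] = c.py; VZ[v] = c.pz;
        double nx1, ny1, nz1, a21;
        face_normal(f, nx1, ny1, nz1, a21);
        VX[u] = ox; VY[u] = oy; VZ[u] = oz;
        VX[v] = ovx; VY[v] = ovy; VZ[v] = ovz;
        // reject collapses creating near-degenerate faces (absolute and
        // relative to the face's previous area) or flipping normals
        if (a21 < 1e-9 || a21 < 1e-6 * a20 ||
            nx0*nx1 + ny0*ny1 + nz0*nz1 <= 0.0) {
          ok = false;
          break;
        }
      }
    }
    if (!ok) continue;

    // perform collapse v -> u at position p
    VX[u] = c.px; VY[u] = c.py; VZ[u] = c.pz;
    Q[u] += Q[v];
    for (int f : vfaces[v]) {
      if (!face_alive[f]) continue;
      bool hasu = false;
      for (int cc = 0; cc < 3; ++cc) if (F[f][cc] == u) hasu = true;
      if (hasu) {
        face_alive[f] = false;
      } else {
        for (int cc = 0; cc < 3; ++cc) if (F[f][cc] == v) F[f][cc] = u;
        vfaces[u].push_back(f);
      }
    }
    vert_alive[v] = false;
    --alive;
    ++version[u];
    ++version[v];
    for (int w : neighbors(u)) push_edge(u, w);
  }

  // compact
  std::vector<int> remap(n0, -1);
  int nv2 = 0;
  for (int i = 0; i < n0; ++i) if (vert_alive[i]) remap[i] = nv2++;
  NumericMatrix Vout(nv2, 3);
  for (int i = 0; i < n0; ++i) {
    if (remap[i] < 0) continue;
    Vout(remap[i], 0) = VX[i];
    Vout(remap[i], 1) = VY[i];
    Vout(remap[i], 2) = VZ[i];
  }
  std::vector<std::array<int,3>> fk;
  for (int f = 0; f < m0; ++f) {
    if (!face_alive[f]) continue;
    int a = remap[F[f][0]], b = remap[F[f][1]], ccc = remap[F[f][2]];
    if (a == b || b == ccc || a == ccc) continue;
    fk.push_back({a + 1, b + 1, ccc + 1});
  }
  IntegerMatrix Fout((int)fk.size(), 3);
  for (size_t f = 0; f < fk.size(); ++f) {
    Fout(f, 0) = fk[f][0]; Fout(f, 1) = fk[f][1]; Fout(f, 2) = fk[f][2];
  }
  return List::create(_["vertices"] = Vout, _["faces"] = Fout);
}
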