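#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include <limits>
#include <unordered_map>
using namespace Rcpp;

// [[Rcpp::export(name = ".cpp_min_dist_idx")]]
List cpp_min_dist_idx(NumericMatrix A, NumericMatrix B) {
  const int n = A.nrow(), p = B.nrow();
  NumericVector d(n);
  IntegerVector idx(n);
  for (int i = 0; i < n; ++i) {
    double ax = A(i, 0), ay = A(i, 1), az = A(i, 2);
    double best = R_PosInf;
    int bi = NA_INTEGER;
    for (int j = 0; j < p; ++j) {
      double dx = B(j, 0) - ax, dy = B(j, 1) - ay, dz = B(j, 2) - az;
      double dd = dx * dx + dy * dy + dz * dz;
      if (dd < best) { best = dd; bi = j + 1; }
    }
    d[i] = std::sqrt(best);
    idx[i] = bi;
  }
  return List::create(_["dist"] = d, _["index"] = idx);
}

// Connected components of an induced subgraph. Adjacency in CSR form
// (0-based ptr of length n+1, 0-based idx), subset as logical mask.
// Returns per-vertex component id (0 = not in subset, else 1..C in
// discovery order by smallest vertex index).
// [[Rcpp::export(name = ".cpp_components_subset")]]
IntegerVector cpp_components_subset(IntegerVector ptr, IntegerVector idx,
                                    LogicalVector subset) {
  const int n = subset.size();
  IntegerVector comp(n, 0);
  std::vector<int> stack;
  int c = 0;
  for (int s = 0; s < n; ++s) {
    if (!subset[s] || comp[s] != 0) continue;
    ++c;
    comp[s] = c;
    stack.push_back(s);
    while (!stack.empty()) {
      int u = stack.back();
      stack.pop_back();
      for (int e = ptr[u]; e < ptr[u + 1]; ++e) {
        int v = idx[e];
        if (subset[v] && comp[v] == 0) {
          comp[v] = c;
          stack.push_back(v);
        }
      }
    }
  }
  return comp;
}

// Consistent face orientation by BFS over the face-adjacency (shared edge)
// graph: flips faces so every shared edge is traversed in opposite
// directions by its two incident faces. Returns a logical flip mask.
// [[Rcpp::export(name = ".cpp_orient_faces")]]
LogicalVector cpp_orient_faces(IntegerMatrix F, int nv) {
  const int m = F.nrow();
  // build edge -> faces map via hashing of undirected edge keys
  std::unordered_map<int64_t, std::vector<int>> e2f;
  e2f.reserve((size_t)m * 3);
  auto ekey = [nv](int a, int b) {
    if (a > b) std::swap(a, b);
    return (int64_t)a * (int64_t)nv + b;
  };
  for (int f = 0; f < m; ++f) {
    int v0 = F(f, 0) - 1, v1 = F(f, 1) - 1, v2 = F(f, 2) - 1;
    e2f[ekey(v0, v1)].push_back(f);
    e2f[ekey(v1, v2)].push_back(f);
    e2f[ekey(v2, v0)].push_back(f);
  }
  LogicalVector flip(m);
  std::vector<int8_t> state(m, 0); // 0 unvisited, 1 keep, 2 flip
  std::vector<int> stack;
  auto dir_edges = [&](int f, bool fl, int out[3][2]) {
    int v0 = F(f, 0) - 1, v1 = F(f, 1) - 1, v2 = F(f, 2) - 1;
    if (fl) std::swap(v1, v2);
    out[0][0] = v0; out[0][1] = v1;
    out[1][0] = v1; out[1][1] = v2;
    out[2][0] = v2; out[2][1] = v0;
  };
  for (int seed = 0; seed < m; ++seed) {
    if (state[seed]) continue;
    state[seed] = 1;
    stack.push_back(seed);
    while (!stack.empty()) {
      int f = stack.back();
      stack.pop_back();
      bool fl = state[f] == 2;
      int de[3][2];
      dir_edges(f, fl, de);
      for (int e = 0; e < 3; ++e) {
        int a = de[e][0], b = de[e][1];
        auto &fs = e2f[ekey(a, b)];
        for (int g : fs) {
          if (g == f || state[g]) continue;
          // does g traverse edge (a,b) in the same direction as f?
          int dg[3][2];
          dir_edges(g, false, dg);
          bool same = false;
          for (int e2 = 0; e2 < 3; ++e2)
            if (dg[e2][0] == a && dg[e2][1] == b) { same = true; break; }
          state[g] = same ? 2 : 1;   // same direction -> must flip g
          stack.push_back(g);
        }
      }
    }
  }
  for (int f = 0; f < m; ++f) flip[f] = state[f] == 2;
  return flip;
}

// Exact 1-D k-means on weighted, sorted support points by dynamic
// programming over contiguous partitions (the optimum of 1-D k-means is
// always a sorted partition). O(k * B^2) with prefix sums.
// [[Rcpp::export(name = ".cpp_kmeans1d_dp")]]
List cpp_kmeans1d_dp(NumericVector x, NumericVector w, int k) {
  const int B = x.size();
  std::vector<double> cw(B + 1, 0.0), cwx(B + 1, 0.0), cwx2(B + 1, 0.0);
  for (int i = 0; i < B; ++i) {
    cw[i + 1] = cw[i] + w[i];
    cwx[i + 1] = cwx[i] + w[i] * x[i];
    cwx2[i + 1] = cwx2[i] + w[i] * x[i] * x[i];
  }
  auto cost = [&](int i, int j) {  // bins i..j inclusive, 0-based
    double W = cw[j + 1] - cw[i];
    if (W <= 0) return 0.0;
    double S = cwx[j + 1] - cwx[i];
    double S2 = cwx2[j + 1] - cwx2[i];
    double c = S2 - S * S / W;
    return c > 0 ? c : 0.0;
  };
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<std::vector<double>> D(k, std::vector<double>(B, INF));
  std::vector<std::vector<int>> back(k, std::vector<int>(B, 0));
  for (int j = 0; j < B; ++j) D[0][j] = cost(0, j);
  for (int q = 1; q < k; ++q) {
    for (int j = q; j < B; ++j) {
      double best = INF;
      int bi = q;
      for (int i = q; i <= j; ++i) {
        double c = D[q - 1][i - 1] + cost(i, j);
        if (c < best) { best = c; bi = i; }
      }
      D[q][j] = best;
      back[q][j] = bi;
    }
  }
  // backtrack cluster boundaries
  IntegerVector assign(B);
  NumericVector centers(k);
  int j = B - 1;
  for (int q = k - 1; q >= 0; --q) {
    int i = q == 0 ? 0 : back[q][j];
    double W = cw[j + 1] - cw[i];
    centers[q] = W > 0 ? (cwx[j + 1] - cwx[i]) / W : x[i];
    for (int t = i; t <= j; ++t) assign[t] = q;
    j = i - 1;
  }
  return List::create(_["assign"] = assign, _["centers"] = centers,
                      _["wcss"] = D[k - 1][B - 1]);
}
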