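#include <Rcpp.h>
#include <algorithm>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

// Vietoris-Rips persistence restricted to homological dimensions 0 and 1
// over Z/2. Dimension 0 is the single-linkage merge structure (Kruskal
// union-find: deaths are the minimum-spanning-tree edge weights); dimension 1
// comes from standard column reduction of the triangle boundary matrix, whose
// pivot rows are the cycle-creating ("positive") edges.
//
// Simplex order: (filtration value, dimension, lexicographic vertex tuple).
// Edge filtration value = its length; triangle value = longest side.

namespace {

struct Edge {
  double w;
  int i, j;  // i < j
};

struct Tri {
  double w;
  int i, j, k;  // i < j < k
};

struct UnionFind {
  std::vector<int> parent;
  explicit UnionFind(int n) : parent(n) {
    for (int v = 0; v < n; ++v) parent[v] = v;
  }
  int find(int v) {
    while (parent[v] != v) {
      parent[v] = parent[parent[v]];
      v = parent[v];
    }
    return v;
  }
  // returns false if already same component
  bool unite(int a, int b) {
    a = find(a); b = find(b);
    if (a == b) return false;
    parent[b] = a;
    return true;
  }
};

// Z/2 columns as fixed-width bitsets over the edge index range; xor is a
// word-wise loop, which keeps the reduction fast under heavy fill-in
struct BitCol {
  std::vector<uint64_t> w;
  explicit BitCol(int words) : w(words, 0) {}
  void set(int i) { w[i >> 6] ^= (uint64_t(1) << (i & 63)); }
  void xor_with(const BitCol& o) {
    for (size_t k = 0; k < w.size(); ++k) w[k] ^= o.w[k];
  }
  // highest set bit at or below `from`; -1 if none
  int low(int from) const {
    int word = from >> 6;
    uint64_t mask = (from & 63) == 63 ? ~uint64_t(0)
                                      : ((uint64_t(1) << ((from & 63) + 1)) - 1);
    for (; word >= 0; --word) {
      uint64_t v = w[word] & mask;
      if (v) return (word << 6) + 63 - __builtin_clzll(v);
      mask = ~uint64_t(0);
    }
    return -1;
  }
};

}  // namespace

// [[Rcpp::export(name = ".rips_pairs_cpp")]]
List rips_pairs_cpp(NumericMatrix dist, double eps_max) {
  const int n = dist.nrow();
  if (n < 1) stop("empty distance matrix");

  std::vector<Edge> edges;
  edges.reserve(static_cast<size_t>(n) * (n - 1) / 2);
  for (int i = 0; i < n - 1; ++i)
    for (int j = i + 1; j < n; ++j)
      if (dist(i, j) <= eps_max) edges.push_back({dist(i, j), i, j});

  std::sort(edges.begin(), edges.end(), [](const Edge& a, const Edge& b) {
    if (a.w != b.w) return a.w < b.w;
    if (a.i != b.i) return a.i < b.i;
    return a.j < b.j;
  });
  const int m = static_cast<int>(edges.size());

  // edge (i,j) -> position in sorted order
  std::vector<int> eidx(static_cast<size_t>(n) * n, -1);
  for (int e = 0; e < m; ++e)
    eidx[static_cast<size_t>(edges[e].i) * n + edges[e].j] = e;

  // --- dimension 0: Kruskal; merging edges are negative, rest positive ---
  UnionFind uf(n);
  std::vector<double> h0_deaths;
  h0_deaths.reserve(n > 0 ? n - 1 : 0);
  std::vector<char> positive(m, 0);
  for (int e = 0; e < m; ++e) {
    if (uf.unite(edges[e].i, edges[e].j)) h0_deaths.push_back(edges[e].w);
    else positive[e] = 1;
  }
  int n_components = n - static_cast<int>(h0_deaths.size());

  // --- dimension 1: reduce triangle boundary columns ---
  std::vector<Tri> tris;
  for (int i = 0; i < n - 2; ++i) {
    for (int j = i + 1; j < n - 1; ++j) {
      double dij = dist(i, j);
      if (dij > eps_max) continue;
      for (int k = j + 1; k < n; ++k) {
        double w = std::max(dij, std::max(dist(i, k), dist(j, k)));
        if (w <= eps_max) tris.push_back({w, i, j, k});
      }
    }
  }
  std::sort(tris.begin(), tris.end(), [](const Tri& a, const Tri& b) {
    if (a.w != b.w) return a.w < b.w;
    if (a.i != b.i) return a.i < b.i;
    if (a.j != b.j) return a.j < b.j;
    return a.k < b.k;
  });

  // pivot edge index -> reduced column owning it (at most one per edge)
  const int words = (m + 63) / 64;
  std::vector<BitCol> cols;
  cols.reserve(std::min(tris.size(), static_cast<size_t>(m)));
  std::vector<int> pivot_of(m, -1);            // edge -> index into cols
  std::vector<double> death_of_edge(m, -1.0);  // pairing for positive edges

  BitCol col(words);
  for (size_t t = 0; t < tris.size(); ++t) {
    const Tri& tr = tris[t];
    int e1 = eidx[static_cast<size_t>(tr.i) * n + tr.j];
    int e2 = eidx[static_cast<size_t>(tr.i) * n + tr.k];
    int e3 = eidx[static_cast<size_t>(tr.j) * n + tr.k];
    std::fill(col.w.begin(), col.w.end(), 0);
    col.set(e1); col.set(e2); col.set(e3);
    int low = col.low(m - 1);
    while (low >= 0 && pivot_of[low] >= 0) {
      col.xor_with(cols[pivot_of[low]]);
      low = col.low(low);
    }
    if (low >= 0) {
      death_of_edge[low] = tr.w;
      pivot_of[low] = static_cast<int>(cols.size());
      cols.push_back(col);
    }
  }

  std::vector<double> h1_birth, h1_death;
  for (int e = 0; e < m; ++e) {
    if (!positive[e]) continue;
    double b = edges[e].w;
    double d = death_of_edge[e] < 0 ? R_PosInf : death_of_edge[e];
    if (d > b) {  // zero-persistence pairs are dropped
      h1_birth.push_back(b);
      h1_death.push_back(d);
    }
  }

  std::sort(h0_deaths.begin(), h0_deaths.end());
  return List::create(_["h0_deaths"] = h0_deaths,
                      _["n_components"] = n_components,
                      _["h1_birth"] = h1_birth,
                      _["h1_death"] = h1_death);
}
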