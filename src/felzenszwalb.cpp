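// Graph-based image segmentation (greedy union-find over sorted edges).
//
// Pixels are graph nodes; 8-neighbour edges are weighted by Euclidean RGB
// distance. Edges are processed in nondecreasing weight order and two
// components merge when the edge weight does not exceed the smaller of the
// two components' internal difference plus k/|C|. A post-pass merges any
// component below min_size into its most similar neighbour (across the
// smallest-weight edge), so no returned segment is smaller than min_size.

#include <Rcpp.h>
#include <algorithm>
#include <vector>

namespace {

struct Edge {
  float w;
  int a, b;
};

struct DisjointSet {
  std::vector<int> parent, rank_, size;
  explicit DisjointSet(int n) : parent(n), rank_(n, 0), size(n, 1) {
    for (int i = 0; i < n; ++i) parent[i] = i;
  }
  int find(int x) {
    while (parent[x] != x) {
      parent[x] = parent[parent[x]];
      x = parent[x];
    }
    return x;
  }
  int join(int x, int y) {
    if (rank_[x] < rank_[y]) std::swap(x, y);
    parent[y] = x;
    size[x] += size[y];
    if (rank_[x] == rank_[y]) ++rank_[x];
    return x;
  }
};

}  // namespace

// [[Rcpp::export(name = ".felzenszwalb_cpp")]]
Rcpp::IntegerMatrix felzenszwalb_cpp(Rcpp::NumericMatrix r,
                                     Rcpp::NumericMatrix g,
                                     Rcpp::NumericMatrix b,
                                     double scale, int min_size) {
  const int h = r.nrow(), w = r.ncol(), n = h * w;
  auto id = [h](int row, int col) { return col * h + row; };

  std::vector<Edge> edges;
  edges.reserve(static_cast<size_t>(n) * 4);
  auto dist = [&](int i, int j) {
    const double dr = r[i] - r[j], dg = g[i] - g[j], db = b[i] - b[j];
    return static_cast<float>(std::sqrt(dr * dr + dg * dg + db * db));
  };
  for (int col = 0; col < w; ++col) {
    for (int row = 0; row < h; ++row) {
      const int i = id(row, col);
      if (row + 1 < h) edges.push_back({dist(i, id(row + 1, col)), i, id(row + 1, col)});
      if (col + 1 < w) edges.push_back({dist(i, id(row, col + 1)), i, id(row, col + 1)});
      if (row + 1 < h && col + 1 < w)
        edges.push_back({dist(i, id(row + 1, col + 1)), i, id(row + 1, col + 1)});
      if (row > 0 && col + 1 < w)
        edges.push_back({dist(i, id(row - 1, col + 1)), i, id(row - 1, col + 1)});
    }
  }
  std::stable_sort(edges.begin(), edges.end(),
                   [](const Edge& x, const Edge& y) { return x.w < y.w; });

  DisjointSet ds(n);
  std::vector<float> internal(n, 0.0f);  // max weight inside each component
  for (const Edge& e : edges) {
    int ra = ds.find(e.a), rb = ds.find(e.b);
    if (ra == rb) continue;
    const double ta = internal[ra] + scale / ds.size[ra];
    const double tb = internal[rb] + scale / ds.size[rb];
    if (e.w <= ta && e.w <= tb) {
      int root = ds.join(ra, rb);
      internal[root] = e.w;
    }
  }

  // enforce the minimum component size
  for (const Edge& e : edges) {
    int ra = ds.find(e.a), rb = ds.find(e.b);
    if (ra != rb && (ds.size[ra] < min_size || ds.size[rb] < min_size)) {
      ds.join(ra, rb);
    }
  }

  Rcpp::IntegerMatrix labels(h, w);
  std::vector<int> relabel(n, 0);
  int next = 0;
  for (int col = 0; col < w; ++col) {
    for (int row = 0; row < h; ++row) {
      int root = ds.find(id(row, col));
      if (relabel[root] == 0) relabel[root] = ++next;
      labels(row, col) = relabel[root];
    }
  }
  return labels;
}
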