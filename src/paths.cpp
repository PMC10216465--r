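#include <Rcpp.h>
#include <queue>
#include <vector>
#include <limits>
using namespace Rcpp;

// Compact adjacency-list view of a dense symmetric matrix. Edge lengths are
// 1 for binary graphs and 1/weight for weighted graphs (the standard
// correlation-to-distance map).
struct AdjList {
  std::vector<std::vector<int>> nb;
  std::vector<std::vector<double>> len;
  int n;
  AdjList(const NumericMatrix &a, bool binary) : n(a.nrow()) {
    nb.resize(n);
    len.resize(n);
    for (int i = 0; i < n; ++i) {
      for (int j = 0; j < n; ++j) {
        double w = a(i, j);
        if (i != j && w > 0) {
          nb[i].push_back(j);
          len[i].push_back(binary ? 1.0 : 1.0 / w);
        }
      }
    }
  }
};

static void dijkstra_from(const AdjList &g, int s, bool binary,
                          std::vector<double> &dist) {
  const double inf = std::numeric_limits<double>::infinity();
  std::fill(dist.begin(), dist.end(), inf);
  dist[s] = 0.0;
  if (binary) {
    std::queue<int> q;
    q.push(s);
    while (!q.empty()) {
      int v = q.front();
      q.pop();
      for (size_t k = 0; k < g.nb[v].size(); ++k) {
        int u = g.nb[v][k];
        if (dist[u] == inf) {
          dist[u] = dist[v] + 1.0;
          q.push(u);
        }
      }
    }
  } else {
    typedef std::pair<double, int> DI;
    std::priority_queue<DI, std::vector<DI>, std::greater<DI>> pq;
    pq.push(DI(0.0, s));
    while (!pq.empty()) {
      DI top = pq.top();
      pq.pop();
      int v = top.second;
      if (top.first > dist[v]) continue;
      for (size_t k = 0; k < g.nb[v].size(); ++k) {
        int u = g.nb[v][k];
        double nd = dist[v] + g.len[v][k];
        if (nd < dist[u]) {
          dist[u] = nd;
          pq.push(DI(nd, u));
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_distance_matrix(NumericMatrix adjacency, bool binary) {
  AdjList g(adjacency, binary);
  NumericMatrix d(g.n, g.n);
  std::vector<double> dist(g.n);
  for (int s = 0; s < g.n; ++s) {
    dijkstra_from(g, s, binary, dist);
    for (int t = 0; t < g.n; ++t) d(s, t) = dist[t];
  }
  return d;
}

// Mean inverse shortest-path length over ordered pairs (1/Inf = 0); the
// global efficiency of the (sub)graph given as a dense matrix.
static double global_efficiency_dense(const NumericMatrix &a, bool binary) {
  AdjList g(a, binary);
  if (g.n < 2) return 0.0;
  std::vector<double> dist(g.n);
  double acc = 0.0;
  for (int s = 0; s < g.n; ++s) {
    dijkstra_from(g, s, binary, dist);
    for (int t = 0; t < g.n; ++t)
      if (t != s && std::isfinite(dist[t])) acc += 1.0 / dist[t];
  }
  return acc / (double(g.n) * double(g.n - 1));
}

// [[Rcpp::export]]
NumericVector cpp_local_efficiency(NumericMatrix adjacency, bool binary) {
  int n = adjacency.nrow();
  NumericVector eloc(n);
  for (int i = 0; i < n; ++i) {
    std::vector<int> nb;
    for (int j = 0; j < n; ++j)
      if (j != i && adjacency(i, j) > 0) nb.push_back(j);
    int m = nb.size();
    if (m < 2) {
      eloc[i] = 0.0;
      continue;
    }
    NumericMatrix sub(m, m);
    for (int p = 0; p < m; ++p)
      for (int q = 0; q < m; ++q) sub(p, q) = adjacency(nb[p], nb[q]);
    eloc[i] = global_efficiency_dense(sub, binary);
  }
  return eloc;
}
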