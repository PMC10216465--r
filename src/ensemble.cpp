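#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Degree-preserving null ensemble: repeated double-edge swaps on the
// topology (10 x |E| attempted swaps per surrogate by default), plus a
// random permutation of the weight multiset for weighted networks. Uses
// R's RNG so results are reproducible under set.seed(). Returns the
// clustering coefficient (binary or Onnela weighted form) and the
// characteristic path length of every surrogate.

struct EdgeSet {
  int n;
  std::vector<int> a, b;      // endpoints
  std::vector<double> w;      // weights
  std::vector<std::vector<char>> exists;
  EdgeSet(const NumericMatrix &adj) : n(adj.nrow()) {
    exists.assign(n, std::vector<char>(n, 0));
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j)
        if (adj(i, j) > 0) {
          a.push_back(i);
          b.push_back(j);
          w.push_back(adj(i, j));
          exists[i][j] = exists[j][i] = 1;
        }
  }
};

static int rand_below(int k) { return (int)std::floor(unif_rand() * k); }

// attempted double-edge swaps; returns number of successful swaps
static int rewire(EdgeSet &e, int attempts) {
  int m = e.a.size();
  int done = 0;
  for (int it = 0; it < attempts; ++it) {
    int e1 = rand_below(m), e2 = rand_below(m);
    if (e1 == e2) continue;
    int x1 = e.a[e1], y1 = e.b[e1], x2 = e.a[e2], y2 = e.b[e2];
    if (unif_rand() < 0.5) std::swap(x2, y2);
    // propose (x1,y2) and (x2,y1)
    if (x1 == y2 || x2 == y1) continue;
    if (x1 == x2 || y1 == y2) continue;
    if (e.exists[x1][y2] || e.exists[x2][y1]) continue;
    e.exists[x1][y1] = e.exists[y1][x1] = 0;
    e.exists[x2][y2] = e.exists[y2][x2] = 0;
    e.exists[x1][y2] = e.exists[y2][x1] = 1;
    e.exists[x2][y1] = e.exists[y1][x2] = 1;
    e.a[e1] = x1; e.b[e1] = y2;
    e.a[e2] = x2; e.b[e2] = y1;
    ++done;
  }
  return done;
}

struct Graph {
  int n;
  std::vector<std::vector<int>> nb;
  std::vector<std::vector<double>> len; // 1/weight (or 1 if binary)
  Graph(const EdgeSet &e, const std::vector<double> &wts, bool binary)
      : n(e.n), nb(e.n), len(e.n) {
    for (size_t k = 0; k < e.a.size(); ++k) {
      double l = binary ? 1.0 : 1.0 / wts[k];
      nb[e.a[k]].push_back(e.b[k]);
      len[e.a[k]].push_back(l);
      nb[e.b[k]].push_back(e.a[k]);
      len[e.b[k]].push_back(l);
    }
  }
};

static double char_path_length(const Graph &g, bool binary) {
  const double inf = std::numeric_limits<double>::infinity();
  double acc = 0.0;
  long cnt = 0;
  std::vector<double> dist(g.n);
  for (int s = 0; s < g.n; ++s) {
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
    for (int t = 0; t < g.n; ++t)
      if (t != s && std::isfinite(dist[t])) {
        acc += dist[t];
        ++cnt;
      }
  }
  return cnt ? acc / cnt : R_NaReal;
}

// mean clustering; binary 2t/k(k-1) or Onnela with weights normalised by
// the network maximum
static double mean_clustering(const EdgeSet &e, const std::vector<double> &wts,
                              bool binary) {
  int n = e.n;
  std::vector<std::vector<int>> nb(n);
  std::vector<std::vector<double>> sw(n, std::vector<double>(n, 0.0));
  double wmax = 0.0;
  for (size_t k = 0; k < wts.size(); ++k)
    if (wts[k] > wmax) wmax = wts[k];
  for (size_t k = 0; k < e.a.size(); ++k) {
    double s = binary ? 1.0 : std::cbrt(wts[k] / wmax);
    nb[e.a[k]].push_back(e.b[k]);
    nb[e.b[k]].push_back(e.a[k]);
    sw[e.a[k]][e.b[k]] = sw[e.b[k]][e.a[k]] = s;
  }
  double acc = 0.0;
  for (int i = 0; i < n; ++i) {
    int k = nb[i].size();
    if (k < 2) continue;
    double t = 0.0;
    for (int p = 0; p < k; ++p)
      for (int q = p + 1; q < k; ++q) {
        int j = nb[i][p], h = nb[i][q];
        if (sw[j][h] > 0) t += sw[i][j] * sw[i][h] * sw[j][h];
      }
    acc += 2.0 * t / (double(k) * double(k - 1));
  }
  return acc / n;
}

// [[Rcpp::export]]
List cpp_null_ensemble(NumericMatrix adjacency, bool binary, int n_random,
                       int niter_mult, bool keep_members) {
  EdgeSet original(adjacency);
  int m = original.a.size();
  NumericVector cp(n_random), lp(n_random);
  IntegerVector swaps(n_random);
  List members(keep_members ? n_random : 0);
  int unchanged = 0;
  for (int r = 0; r < n_random; ++r) {
    EdgeSet e = original;
    swaps[r] = rewire(e, niter_mult * m);
    // permuted weight multiset over the rewired topology
    std::vector<double> wts = original.w;
    if (!binary) {
      for (int k = m - 1; k > 0; --k) std::swap(wts[k], wts[rand_below(k + 1)]);
    }
    bool same = true;
    for (int k = 0; k < m && same; ++k)
      if (!original.exists[e.a[k]][e.b[k]]) same = false;
    if (same) ++unchanged;
    cp[r] = mean_clustering(e, wts, binary);
    Graph g(e, wts, binary);
    lp[r] = char_path_length(g, binary);
    if (keep_members) {
      NumericMatrix el(m, 3);
      for (int k = 0; k < m; ++k) {
        el(k, 0) = e.a[k] + 1;
        el(k, 1) = e.b[k] + 1;
        el(k, 2) = binary ? 1.0 : wts[k];
      }
      members[r] = el;
    }
  }
  return List::create(
      _["Cp_rand"] = cp, _["Lp_rand"] = lp, _["swaps"] = swaps,
      _["unchanged"] = unchanged, _["members"] = members);
}
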