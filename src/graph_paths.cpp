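#include <Rcpp.h>
#include <queue>
#include <vector>
#include <limits>
using namespace Rcpp;

// Weighted shortest paths on a dense length matrix (0 or NA = no edge).
// Ties on total length are broken toward the minimum hop count, so the
// reported hop counts are well defined even when several geodesics exist.

static const double INF = std::numeric_limits<double>::infinity();

struct QItem {
  double dist;
  int hops;
  int node;
};
struct QCmp {
  bool operator()(const QItem& a, const QItem& b) const {
    if (a.dist != b.dist) return a.dist > b.dist;
    return a.hops > b.hops;
  }
};

// [[Rcpp::export(name = ".cpp_dijkstra_all")]]
List cpp_dijkstra_all(NumericMatrix len) {
  int n = len.nrow();
  NumericMatrix dist(n, n), hops(n, n);

  // adjacency lists
  std::vector<std::vector<std::pair<int, double> > > adj(n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) {
      double l = len(i, j);
      if (i != j && R_finite(l) && l > 0) adj[i].push_back(std::make_pair(j, l));
    }

  std::vector<double> d(n);
  std::vector<int> h(n);
  for (int s = 0; s < n; ++s) {
    std::fill(d.begin(), d.end(), INF);
    std::fill(h.begin(), h.end(), -1);
    d[s] = 0.0; h[s] = 0;
    std::priority_queue<QItem, std::vector<QItem>, QCmp> pq;
    pq.push(QItem{0.0, 0, s});
    while (!pq.empty()) {
      QItem it = pq.top(); pq.pop();
      if (it.dist > d[it.node] ||
          (it.dist == d[it.node] && it.hops > h[it.node])) continue;
      int u = it.node;
      for (size_t k = 0; k < adj[u].size(); ++k) {
        int v = adj[u][k].first;
        double nd = it.dist + adj[u][k].second;
        int nh = it.hops + 1;
        if (nd < d[v] || (nd == d[v] && nh < h[v])) {
          d[v] = nd; h[v] = nh;
          pq.push(QItem{nd, nh, v});
        }
      }
    }
    for (int t = 0; t < n; ++t) {
      dist(s, t) = d[t];
      hops(s, t) = (h[t] < 0) ? NA_REAL : (double)h[t];
    }
  }
  return List::create(_["dist"] = dist, _["hops"] = hops);
}

// Brandes betweenness on weighted undirected graphs. Equal-length parallel
// geodesics are detected with relative tolerance `tol` and counted
// fractionally through the standard dependency accumulation.
// [[Rcpp::export(name = ".cpp_betweenness_w")]]
NumericVector cpp_betweenness_w(NumericMatrix len, double tol) {
  int n = len.nrow();
  std::vector<std::vector<std::pair<int, double> > > adj(n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) {
      double l = len(i, j);
      if (i != j && R_finite(l) && l > 0) adj[i].push_back(std::make_pair(j, l));
    }

  NumericVector bc(n);
  std::vector<double> d(n), sigma(n), delta(n);
  std::vector<std::vector<int> > pred(n);
  std::vector<int> order; order.reserve(n);

  for (int s = 0; s < n; ++s) {
    std::fill(d.begin(), d.end(), INF);
    std::fill(sigma.begin(), sigma.end(), 0.0);
    std::fill(delta.begin(), delta.end(), 0.0);
    for (int i = 0; i < n; ++i) pred[i].clear();
    order.clear();
    d[s] = 0.0; sigma[s] = 1.0;

    std::priority_queue<QItem, std::vector<QItem>, QCmp> pq;
    pq.push(QItem{0.0, 0, s});
    std::vector<char> done(n, 0);
    while (!pq.empty()) {
      QItem it = pq.top(); pq.pop();
      int u = it.node;
      if (done[u]) continue;
      done[u] = 1;
      order.push_back(u);
      for (size_t k = 0; k < adj[u].size(); ++k) {
        int v = adj[u][k].first;
        double nd = d[u] + adj[u][k].second;
        bool unreached = !R_finite(d[v]);
        double eps = unreached ? 0.0
                               : tol * (std::abs(nd) + std::abs(d[v]) + 1.0);
        if (unreached || nd < d[v] - eps) {
          d[v] = nd;
          sigma[v] = sigma[u];
          pred[v].clear();
          pred[v].push_back(u);
          pq.push(QItem{nd, 0, v});
        } else if (std::abs(nd - d[v]) <= eps && !done[v]) {
          sigma[v] += sigma[u];
          pred[v].push_back(u);
        }
      }
    }
    for (int i = (int)order.size() - 1; i > 0; --i) {
      int w = order[i];
      for (size_t k = 0; k < pred[w].size(); ++k) {
        int u = pred[w][k];
        delta[u] += sigma[u] / sigma[w] * (1.0 + delta[w]);
      }
      bc[w] += delta[w];
    }
  }
  // undirected: each pair counted from both endpoints
  for (int i = 0; i < n; ++i) bc[i] /= 2.0;
  return bc;
}
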