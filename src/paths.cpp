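#include <Rcpp.h>
#include <queue>
#include <vector>
#include <utility>
using namespace Rcpp;

// All-pairs shortest path lengths on a weighted graph where the length of an
// edge with weight w > 0 is 1/w (stronger connections are shorter).
// Unreachable pairs get +Inf.  Dijkstra from every source; weights must be
// nonnegative, which the weighted_network class guarantees.
// [[Rcpp::export]]
NumericMatrix dist_shortest_cpp(NumericMatrix w) {
  const int n = w.nrow();
  NumericMatrix d(n, n);
  std::vector<std::vector<std::pair<int, double> > > adj(n);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      if (i != j && w(i, j) > 0.0)
        adj[i].push_back(std::make_pair(j, 1.0 / w(i, j)));
    }
  }
  typedef std::pair<double, int> pdi;
  std::vector<double> dist(n);
  for (int s = 0; s < n; ++s) {
    std::fill(dist.begin(), dist.end(), R_PosInf);
    dist[s] = 0.0;
    std::priority_queue<pdi, std::vector<pdi>, std::greater<pdi> > pq;
    pq.push(std::make_pair(0.0, s));
    while (!pq.empty()) {
      double du = pq.top().first;
      int u = pq.top().second;
      pq.pop();
      if (du > dist[u]) continue;
      for (size_t k = 0; k < adj[u].size(); ++k) {
        int v = adj[u][k].first;
        double nd = du + adj[u][k].second;
        if (nd < dist[v]) {
          dist[v] = nd;
          pq.push(std::make_pair(nd, v));
        }
      }
    }
    for (int j = 0; j < n; ++j) d(s, j) = dist[j];
    d(s, s) = 0.0;
  }
  return d;
}
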