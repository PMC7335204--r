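#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// All-pairs shortest paths under the length transform l_ij = 1/w_ij
// (w_ij = 0 means no edge), plus Brandes betweenness with shortest-path
// counting. Path-length ties are detected with a small absolute tolerance
// so exactly representable equal-length alternatives are counted.
//
// Betweenness sums sigma_st(v)/sigma_st over *ordered* pairs (s,t):
// one Dijkstra per source, no halving.
// [[Rcpp::export]]
List graph_paths_cpp(NumericMatrix W, double eps = 1e-10) {
  const int n = W.nrow();
  NumericMatrix D(n, n);
  NumericVector BC(n);
  std::fill(D.begin(), D.end(), R_PosInf);

  std::vector<std::vector<std::pair<int, double> > > adj(n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (i != j && W(i, j) > 0.0)
        adj[i].push_back(std::make_pair(j, 1.0 / W(i, j)));

  typedef std::pair<double, int> PQItem;
  std::vector<double> dist(n), sigma(n), delta(n);
  std::vector<bool> done(n);
  std::vector<std::vector<int> > pred(n);
  std::vector<int> order;

  for (int s = 0; s < n; ++s) {
    std::fill(dist.begin(), dist.end(), R_PosInf);
    std::fill(sigma.begin(), sigma.end(), 0.0);
    std::fill(delta.begin(), delta.end(), 0.0);
    std::fill(done.begin(), done.end(), false);
    for (int i = 0; i < n; ++i) pred[i].clear();
    order.clear();

    dist[s] = 0.0;
    sigma[s] = 1.0;
    std::priority_queue<PQItem, std::vector<PQItem>, std::greater<PQItem> > pq;
    pq.push(std::make_pair(0.0, s));

    while (!pq.empty()) {
      double d = pq.top().first;
      int u = pq.top().second;
      pq.pop();
      if (done[u]) continue;
      done[u] = true;
      order.push_back(u);
      for (size_t k = 0; k < adj[u].size(); ++k) {
        int v = adj[u][k].first;
        if (done[v]) continue;
        double nd = d + adj[u][k].second;
        if (nd < dist[v] - eps) {
          dist[v] = nd;
          sigma[v] = sigma[u];
          pred[v].clear();
          pred[v].push_back(u);
          pq.push(std::make_pair(nd, v));
        } else if (std::abs(nd - dist[v]) <= eps) {
          sigma[v] += sigma[u];
          pred[v].push_back(u);
        }
      }
    }

    for (int k = (int)order.size() - 1; k >= 0; --k) {
      int w = order[k];
      for (size_t j = 0; j < pred[w].size(); ++j) {
        int u = pred[w][j];
        delta[u] += sigma[u] / sigma[w] * (1.0 + delta[w]);
      }
      if (w != s) BC[w] += delta[w];
    }
    for (int j = 0; j < n; ++j) D(s, j) = dist[j];
  }

  return List::create(_["distances"] = D, _["betweenness"] = BC);
}
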