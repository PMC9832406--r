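// Integer min-cost flow by successive shortest paths with node potentials.
// Costs arrive as integer-valued doubles (|cost| < 2^53) and are handled in
// 64-bit integer arithmetic so path comparisons are exact.

#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cstdint>
#include <cmath>

using namespace Rcpp;

// [[Rcpp::export]]
List mcf_run(int n_nodes, IntegerVector from, IntegerVector to,
             IntegerVector cap, NumericVector cost,
             int source, int sink, int flow_target) {
  const int m = from.size();
  if (to.size() != m || cap.size() != m || cost.size() != m)
    stop("arc vectors must have equal length");

  std::vector<int> head(n_nodes, -1), nxt, eto, ecap;
  std::vector<int64_t> ecost;
  nxt.reserve(2 * m); eto.reserve(2 * m);
  ecap.reserve(2 * m); ecost.reserve(2 * m);
  auto add_edge = [&](int u, int v, int c, int64_t w) {
    eto.push_back(v); ecap.push_back(c); ecost.push_back(w);
    nxt.push_back(head[u]); head[u] = (int)eto.size() - 1;
    eto.push_back(u); ecap.push_back(0); ecost.push_back(-w);
    nxt.push_back(head[v]); head[v] = (int)eto.size() - 1;
  };
  for (int i = 0; i < m; ++i) {
    int u = from[i] - 1, v = to[i] - 1;
    if (u < 0 || u >= n_nodes || v < 0 || v >= n_nodes)
      stop("arc endpoint out of range");
    add_edge(u, v, cap[i], (int64_t) std::llround(cost[i]));
  }

  const int64_t INF = std::numeric_limits<int64_t>::max() / 4;
  const int s = source - 1, t = sink - 1;

  // Initial potentials: Bellman-Ford from the source over the zero-flow
  // residual graph (arc costs may be negative).
  std::vector<int64_t> pot(n_nodes, 0);
  {
    std::vector<int64_t> d(n_nodes, INF);
    d[s] = 0;
    for (int it = 0; it < n_nodes; ++it) {
      bool changed = false;
      for (int u = 0; u < n_nodes; ++u) {
        if (d[u] >= INF) continue;
        for (int e = head[u]; e != -1; e = nxt[e]) {
          if (ecap[e] > 0 && d[u] + ecost[e] < d[eto[e]]) {
            d[eto[e]] = d[u] + ecost[e];
            changed = true;
          }
        }
      }
      if (!changed) break;
    }
    for (int u = 0; u < n_nodes; ++u) pot[u] = d[u] < INF ? d[u] : 0;
  }

  std::vector<int64_t> dist(n_nodes);
  std::vector<int> par(n_nodes);
  std::vector<char> done(n_nodes);
  int flow = 0;
  double total_cost = 0.0;  // reporting only; objective is recomputed in R

  while (flow < flow_target) {
    // Dijkstra on reduced costs, O(V^2): V is small (patients + clinics).
    std::fill(dist.begin(), dist.end(), INF);
    std::fill(done.begin(), done.end(), 0);
    std::fill(par.begin(), par.end(), -1);
    dist[s] = 0;
    for (;;) {
      int u = -1;
      int64_t best = INF;
      for (int i = 0; i < n_nodes; ++i)
        if (!done[i] && dist[i] < best) { best = dist[i]; u = i; }
      if (u < 0) break;
      done[u] = 1;
      for (int e = head[u]; e != -1; e = nxt[e]) {
        if (ecap[e] <= 0) continue;
        int v = eto[e];
        int64_t nd = dist[u] + ecost[e] + pot[u] - pot[v];
        if (nd < dist[v]) { dist[v] = nd; par[v] = e; }
      }
    }
    if (dist[t] >= INF) break;  // no augmenting path left
    for (int i = 0; i < n_nodes; ++i)
      if (dist[i] < INF) pot[i] += dist[i];

    int push = flow_target - flow;
    for (int v = t; v != s; v = eto[par[v] ^ 1])
      push = std::min(push, ecap[par[v]]);
    for (int v = t; v != s; v = eto[par[v] ^ 1]) {
      int e = par[v];
      ecap[e] -= push;
      ecap[e ^ 1] += push;
      total_cost += (double) push * (double) ecost[e];
    }
    flow += push;
  }

  IntegerVector arc_flow(m);
  for (int i = 0; i < m; ++i) arc_flow[i] = ecap[2 * i + 1];
  return List::create(_["flow"] = arc_flow,
                      _["total_cost"] = total_cost,
                      _["flow_value"] = flow);
}
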