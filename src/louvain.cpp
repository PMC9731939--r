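#include <Rcpp.h>
#include <vector>
#include <cmath>
#include "rng.h"

using namespace Rcpp;

// Multilevel modularity optimization (Louvain) following the reference
// two-phase formulation: repeated local node moves maximizing modularity
// gain, then aggregation of communities into a weighted graph with
// self-loops, iterated until the modularity gain between levels drops
// below a small threshold. Node visit order and the order in which
// candidate neighbour communities are examined are shuffled each pass,
// which is the source of run-to-run stochasticity.

namespace {

const double MIN_GAIN = 1e-7;

struct WGraph {
  int n;
  // adjacency excluding self-loops
  std::vector<std::vector<std::pair<int, double> > > adj;
  std::vector<double> loops;  // self-loop weight per node (counted once)
  double total_weight;        // sum of edge weights, self-loops once

  explicit WGraph(int n_) : n(n_), adj(n_), loops(n_, 0.0), total_weight(0.0) {}

  void add_edge(int u, int v, double w) {
    if (u == v) {
      loops[u] += w;
    } else {
      adj[u].push_back(std::make_pair(v, w));
      adj[v].push_back(std::make_pair(u, w));
    }
    total_weight += w;
  }

  double gdegree(int u) const {
    double d = 2.0 * loops[u];
    for (size_t k = 0; k < adj[u].size(); ++k) d += adj[u][k].second;
    return d;
  }
};

struct Status {
  std::vector<int> node2com;
  std::vector<double> degrees;   // per community: sum of weighted degrees
  std::vector<double> internals; // per community: internal edge weight (loops once)
  std::vector<double> gdegrees;  // per node
  std::vector<double> loops;     // per node
  double total_weight;

  void init(const WGraph& g) {
    int n = g.n;
    node2com.resize(n);
    degrees.assign(n, 0.0);
    internals.assign(n, 0.0);
    gdegrees.resize(n);
    loops.resize(n);
    total_weight = g.total_weight;
    for (int u = 0; u < n; ++u) {
      node2com[u] = u;
      gdegrees[u] = g.gdegree(u);
      loops[u] = g.loops[u];
      degrees[u] = gdegrees[u];
      internals[u] = g.loops[u];
    }
  }

  double modularity(double resolution) const {
    double m = total_weight;
    double q = 0.0;
    for (size_t c = 0; c < degrees.size(); ++c) {
      if (degrees[c] > 0.0 || internals[c] > 0.0) {
        double term = degrees[c] / (2.0 * m);
        q += resolution * internals[c] / m - term * term;
      }
    }
    return q;
  }
};

// sum of weights from `node` to each neighbouring community (self-loops excluded),
// communities listed in first-encounter order
void neighcom(const WGraph& g, const Status& st, int node,
              std::vector<int>& coms, std::vector<double>& wts,
              std::vector<double>& scratch, std::vector<int>& touched) {
  coms.clear();
  wts.clear();
  const std::vector<std::pair<int, double> >& nb = g.adj[node];
  for (size_t k = 0; k < nb.size(); ++k) {
    int c = st.node2com[nb[k].first];
    if (scratch[c] == 0.0) touched.push_back(c);
    scratch[c] += nb[k].second;
  }
  for (size_t k = 0; k < nb.size(); ++k) {
    int c = st.node2com[nb[k].first];
    if (scratch[c] != 0.0) {
      coms.push_back(c);
      wts.push_back(scratch[c]);
      scratch[c] = 0.0;
    }
  }
  touched.clear();
}

void one_level(const WGraph& g, Status& st, double resolution, CdRng& rng) {
  bool modified = true;
  double cur_mod = st.modularity(resolution);
  double new_mod = cur_mod;
  std::vector<int> order(g.n);
  for (int i = 0; i < g.n; ++i) order[i] = i;
  std::vector<double> scratch(g.n, 0.0);
  std::vector<int> touched;
  std::vector<int> coms;
  std::vector<double> wts;
  std::vector<int> idx;

  while (modified) {
    cur_mod = new_mod;
    modified = false;
    rng.shuffle(order);
    for (int oi = 0; oi < g.n; ++oi) {
      int node = order[oi];
      int com_node = st.node2com[node];
      double degc_totw = st.gdegrees[node] / (st.total_weight * 2.0);
      neighcom(g, st, node, coms, wts, scratch, touched);
      double w_own = 0.0;
      for (size_t k = 0; k < coms.size(); ++k)
        if (coms[k] == com_node) { w_own = wts[k]; break; }
      double remove_cost = -w_own +
        resolution * (st.degrees[com_node] - st.gdegrees[node]) * degc_totw;
      // remove
      st.degrees[com_node] -= st.gdegrees[node];
      st.internals[com_node] -= w_own + st.loops[node];
      st.node2com[node] = -1;

      int best_com = com_node;
      double best_incr = 0.0;
      idx.resize(coms.size());
      for (size_t k = 0; k < coms.size(); ++k) idx[k] = (int)k;
      rng.shuffle(idx);
      for (size_t k = 0; k < idx.size(); ++k) {
        int com = coms[idx[k]];
        double incr = remove_cost + wts[idx[k]] -
          resolution * st.degrees[com] * degc_totw;
        if (incr > best_incr) {
          best_incr = incr;
          best_com = com;
        }
      }
      // insert
      double w_best = 0.0;
      for (size_t k = 0; k < coms.size(); ++k)
        if (coms[k] == best_com) { w_best = wts[k]; break; }
      st.node2com[node] = best_com;
      st.degrees[best_com] += st.gdegrees[node];
      st.internals[best_com] += w_best + st.loops[node];
      if (best_com != com_node) modified = true;
    }
    new_mod = st.modularity(resolution);
    if (new_mod - cur_mod < MIN_GAIN) break;
  }
}

// renumber communities in order of first appearance over node index
std::vector<int> renumber(const std::vector<int>& node2com, int& k_out) {
  std::vector<int> remap(node2com.size(), -1);
  std::vector<int> out(node2com.size());
  int k = 0;
  for (size_t i = 0; i < node2com.size(); ++i) {
    int c = node2com[i];
    if (remap[c] < 0) remap[c] = k++;
    out[i] = remap[c];
  }
  k_out = k;
  return out;
}

WGraph induced_graph(const std::vector<int>& part, int k, const WGraph& g) {
  WGraph ind(k);
  // aggregate inter-community weights; intra weight becomes a self-loop
  std::vector<std::vector<double> > acc(k);
  std::vector<std::vector<int> > accc(k);
  std::vector<double> scratch(k, 0.0);
  for (int u = 0; u < g.n; ++u) {
    int cu = part[u];
    if (g.loops[u] != 0.0) ind.loops[cu] += g.loops[u];
    for (size_t e = 0; e < g.adj[u].size(); ++e) {
      int v = g.adj[u][e].first;
      if (v < u) continue;  // each undirected edge once
      int cv = part[v];
      double w = g.adj[u][e].second;
      if (cu == cv) {
        ind.loops[cu] += w;
      } else {
        int a = cu < cv ? cu : cv;
        int b = cu < cv ? cv : cu;
        accc[a].push_back(b);
        acc[a].push_back(w);
      }
    }
  }
  ind.total_weight = 0.0;
  for (int c = 0; c < k; ++c) ind.total_weight += ind.loops[c];
  for (int a = 0; a < k; ++a) {
    // merge duplicate (a,b) pairs
    std::vector<int> seen;
    for (size_t j = 0; j < accc[a].size(); ++j) {
      int b = accc[a][j];
      if (scratch[b] == 0.0) seen.push_back(b);
      scratch[b] += acc[a][j];
    }
    for (size_t j = 0; j < seen.size(); ++j) {
      int b = seen[j];
      ind.adj[a].push_back(std::make_pair(b, scratch[b]));
      ind.adj[b].push_back(std::make_pair(a, scratch[b]));
      ind.total_weight += scratch[b];
      scratch[b] = 0.0;
    }
  }
  return ind;
}

}  // namespace

// [[Rcpp::export]]
IntegerVector louvain_cpp(int n, IntegerVector from, IntegerVector to,
                          NumericVector weight, double resolution,
                          double seed) {
  CdRng rng((uint64_t)seed);
  WGraph g(n);
  for (int e = 0; e < from.size(); ++e)
    g.add_edge(from[e], to[e], weight[e]);
  if (g.total_weight <= 0.0) stop("graph has no edges");

  Status st;
  st.init(g);
  one_level(g, st, resolution, rng);
  double mod = st.modularity(resolution);
  int k = 0;
  std::vector<int> partition = renumber(st.node2com, k);
  std::vector<int> final_part = partition;  // node -> community at finest accepted level
  WGraph cur = induced_graph(partition, k, g);

  while (true) {
    st.init(cur);
    one_level(cur, st, resolution, rng);
    double new_mod = st.modularity(resolution);
    if (new_mod - mod < MIN_GAIN) break;
    mod = new_mod;
    partition = renumber(st.node2com, k);
    for (int u = 0; u < n; ++u) final_part[u] = partition[final_part[u]];
    cur = induced_graph(partition, k, cur);
  }

  IntegerVector out(n);
  for (int u = 0; u < n; ++u) out[u] = final_part[u] + 1;  // 1-based labels
  return out;
}
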