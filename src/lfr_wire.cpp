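#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cfenv>
#include "rng.h"

using namespace Rcpp;

// Wiring stage of the LFR-style benchmark generator. Nodes are visited
// community by community; each node first tops its current degree up to
// its intra-community target round(deg * (1 - mu)) by linking to random
// members of its own community, then up to its full target degree by
// linking to random nodes of other communities. Edges received from
// previously-wired nodes count towards the targets, which is what gives
// the generator its characteristic realized degree and mixing (both
// slightly above nominal). Self-loops and duplicate edges are never
// created; a bounded number of rejected draws per node guards against
// saturated communities. A node drawing itself during the intra phase
// consumes two degree slots without creating an edge (at most once per
// node), mirroring the reference construction where that draw forms a
// self-loop whose slots are then topped up with inter-community edges;
// this keeps the realized mixing of the emulated graphs faithful while
// the returned graph stays simple.

namespace {
// round-half-to-even, matching the reference generator's rounding
inline int round_even(double x) {
  double f = std::floor(x);
  double diff = x - f;
  if (diff > 0.5) return (int)f + 1;
  if (diff < 0.5) return (int)f;
  int fi = (int)f;
  return (fi % 2 == 0) ? fi : fi + 1;
}

inline bool has_edge(const std::vector<std::vector<int> >& adj, int u, int v) {
  const std::vector<int>& a = adj[u].size() <= adj[v].size() ? adj[u] : adj[v];
  int w = adj[u].size() <= adj[v].size() ? v : u;
  for (size_t k = 0; k < a.size(); ++k)
    if (a[k] == w) return true;
  return false;
}
}  // namespace

// [[Rcpp::export]]
IntegerMatrix lfr_wire_cpp(IntegerVector deg_seq, IntegerVector membership,
                           double mu, double seed) {
  int n = deg_seq.size();
  CdRng rng((uint64_t)seed);

  int n_com = 0;
  for (int i = 0; i < n; ++i)
    if (membership[i] + 1 > n_com) n_com = membership[i] + 1;
  std::vector<std::vector<int> > members(n_com);
  for (int i = 0; i < n; ++i) members[membership[i]].push_back(i);

  std::vector<std::vector<int> > adj(n);
  std::vector<int> deg(n, 0);
  std::vector<bool> self_drawn(n, false);
  std::vector<int> e_from, e_to;
  e_from.reserve(n * 12);
  e_to.reserve(n * 12);

  const int max_tries = 5000;

  for (int c = 0; c < n_com; ++c) {
    const std::vector<int>& mem = members[c];
    int sz = (int)mem.size();
    for (int mi = 0; mi < sz; ++mi) {
      int u = mem[mi];
      int intra_target = round_even(deg_seq[u] * (1.0 - mu));
      int tries = 0;
      while (deg[u] < intra_target && tries++ < max_tries) {
        int v = mem[rng.randint(sz)];
        if (v == u) {
          if (!self_drawn[u]) {
            self_drawn[u] = true;
            deg[u] += 2;  // phantom self-loop slots, no edge created
          }
          continue;
        }
        if (has_edge(adj, u, v)) continue;
        adj[u].push_back(v);
        adj[v].push_back(u);
        deg[u]++; deg[v]++;
        e_from.push_back(u); e_to.push_back(v);
      }
      tries = 0;
      while (deg[u] < deg_seq[u] && tries++ < max_tries) {
        int v = rng.randint(n);
        if (membership[v] == c || has_edge(adj, u, v)) continue;
        adj[u].push_back(v);
        adj[v].push_back(u);
        deg[u]++; deg[v]++;
        e_from.push_back(u); e_to.push_back(v);
      }
    }
  }

  IntegerMatrix out((int)e_from.size(), 2);
  for (size_t e = 0; e < e_from.size(); ++e) {
    out(e, 0) = e_from[e] + 1;
    out(e, 1) = e_to[e] + 1;
  }
  return out;
}
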