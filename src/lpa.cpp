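#include <Rcpp.h>
#include <vector>
#include "rng.h"

using namespace Rcpp;

// Asynchronous label propagation (Raghavan et al. variant): every node
// starts with a unique label; nodes are visited in a fresh uniform-random
// order each sweep; a node keeps its label if it is already among the
// modal labels of its neighbours, otherwise it adopts one modal label
// uniformly at random. Converges when a full sweep changes nothing.

// [[Rcpp::export]]
IntegerVector lpa_cpp(int n, IntegerVector from, IntegerVector to,
                      double seed, int max_sweeps) {
  CdRng rng((uint64_t)seed);
  std::vector<std::vector<int> > adj(n);
  for (int e = 0; e < from.size(); ++e) {
    adj[from[e]].push_back(to[e]);
    adj[to[e]].push_back(from[e]);
  }

  std::vector<int> labels(n);
  for (int i = 0; i < n; ++i) labels[i] = i;
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;

  std::vector<int> cnt(n, 0);
  std::vector<int> touched;
  std::vector<int> modal;

  for (int sweep = 0; sweep < max_sweeps; ++sweep) {
    rng.shuffle(order);
    bool changed = false;
    for (int oi = 0; oi < n; ++oi) {
      int u = order[oi];
      if (adj[u].empty()) continue;
      touched.clear();
      int best = 0;
      for (size_t k = 0; k < adj[u].size(); ++k) {
        int lab = labels[adj[u][k]];
        if (cnt[lab] == 0) touched.push_back(lab);
        if (++cnt[lab] > best) best = cnt[lab];
      }
      modal.clear();
      bool own_modal = false;
      for (size_t k = 0; k < touched.size(); ++k) {
        if (cnt[touched[k]] == best) {
          modal.push_back(touched[k]);
          if (touched[k] == labels[u]) own_modal = true;
        }
        cnt[touched[k]] = 0;
      }
      if (!own_modal) {
        labels[u] = modal[modal.size() == 1 ? 0 : rng.randint((int)modal.size())];
        changed = true;
      }
    }
    if (!changed) break;
  }

  // renumber labels to 1..k in order of first appearance
  std::vector<int> remap(n, 0);
  int k = 0;
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    int lab = labels[i];
    if (remap[lab] == 0) remap[lab] = ++k;
    out[i] = remap[lab];
  }
  return out;
}
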