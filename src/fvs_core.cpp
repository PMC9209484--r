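#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// Directed-cycle test on the subgraph induced by keep, via Kahn's algorithm.
// A kept self-loop is a cycle of length 1. Edges are 0-based node indices.
// [[Rcpp::export]]
bool has_cycle_cpp(int n, IntegerVector from, IntegerVector to, LogicalVector keep) {
  int m = from.size();
  std::vector<std::vector<int> > out(n);
  std::vector<int> indeg(n, 0);
  for (int e = 0; e < m; ++e) {
    int u = from[e], v = to[e];
    if (!keep[u] || !keep[v]) continue;
    if (u == v) return true;
    out[u].push_back(v);
    indeg[v]++;
  }
  std::queue<int> q;
  int kept = 0;
  for (int v = 0; v < n; ++v) {
    if (!keep[v]) continue;
    ++kept;
    if (indeg[v] == 0) q.push(v);
  }
  int removed = 0;
  while (!q.empty()) {
    int u = q.front(); q.pop();
    ++removed;
    for (size_t i = 0; i < out[u].size(); ++i) {
      int v = out[u][i];
      if (--indeg[v] == 0) q.push(v);
    }
  }
  return removed < kept;
}

// SA-FVSP: simulated-annealing local search for a near-minimum feedback
// vertex set. The state is a topologically ordered acyclic induced subgraph
// S; a move inserts a node just after its last in-neighbour in S or just
// before its first out-neighbour, evicting order-violating neighbours.
// Energy is |V \ S|; Metropolis acceptance with geometric cooling. Nodes
// carrying self-loops can never enter S. Uses R's RNG, so results are
// reproducible under set.seed(). Returns membership of the best S found.
// [[Rcpp::export]]
LogicalVector sa_fvsp_cpp(int n, IntegerVector from, IntegerVector to,
                          double t0, double cooling, int moves_per_level,
                          int stagnation_levels) {
  int m = from.size();
  std::vector<std::vector<int> > outn(n), inn(n);
  std::vector<bool> selfloop(n, false);
  for (int e = 0; e < m; ++e) {
    int u = from[e], v = to[e];
    if (u == v) { selfloop[u] = true; continue; }
    outn[u].push_back(v);
    inn[v].push_back(u);
  }
  std::vector<int> eligible;
  for (int v = 0; v < n; ++v) if (!selfloop[v]) eligible.push_back(v);
  int n_elig = (int)eligible.size();

  std::vector<int> seq;             // topological order of S
  std::vector<int> pos(n, -1);      // index in seq, -1 if not in S
  std::vector<int> notS = eligible; // candidates outside S
  std::vector<int> notS_idx(n, -1);
  for (size_t i = 0; i < notS.size(); ++i) notS_idx[notS[i]] = (int)i;

  std::vector<bool> bestS(n, false);
  int best_size = 0;
  double temp = t0;
  int stagnation = 0;

  auto remove_from_notS = [&](int v) {
    int i = notS_idx[v];
    int last = notS.back();
    notS[i] = last; notS_idx[last] = i;
    notS.pop_back(); notS_idx[v] = -1;
  };
  auto add_to_notS = [&](int v) {
    notS_idx[v] = (int)notS.size();
    notS.push_back(v);
  };

  while (n_elig > 0 && best_size < n_elig && stagnation < stagnation_levels) {
    bool improved = false;
    for (int mv = 0; mv < moves_per_level && !notS.empty(); ++mv) {
      int v = notS[(int)(unif_rand() * notS.size())];
      // candidate insertion positions
      int p_minus = 0, p_plus = (int)seq.size();
      for (size_t i = 0; i < inn[v].size(); ++i) {
        int u = inn[v][i];
        if (pos[u] >= 0 && pos[u] + 1 > p_minus) p_minus = pos[u] + 1;
      }
      for (size_t i = 0; i < outn[v].size(); ++i) {
        int w = outn[v][i];
        if (pos[w] >= 0 && pos[w] < p_plus) p_plus = pos[w];
      }
      bool use_minus = unif_rand() < 0.5;
      int p = use_minus ? p_minus : p_plus;
      // conflicts to evict
      std::vector<int> evict;
      if (use_minus) {
        for (size_t i = 0; i < outn[v].size(); ++i) {
          int w = outn[v][i];
          if (pos[w] >= 0 && pos[w] < p) evict.push_back(w);
        }
      } else {
        for (size_t i = 0; i < inn[v].size(); ++i) {
          int u = inn[v][i];
          if (pos[u] >= 0 && pos[u] >= p) evict.push_back(u);
        }
      }
      int delta = (int)evict.size() - 1; // change in |V \ S|
      if (delta > 0 && unif_rand() >= std::exp(-delta / temp)) continue;
      // apply: drop evicted, insert v at p (adjusted for removals before p)
      int first_dirty = p;
      if (!evict.empty()) {
        std::vector<bool> is_ev(n, false);
        int shift = 0;
        for (size_t i = 0; i < evict.size(); ++i) {
          is_ev[evict[i]] = true;
          if (pos[evict[i]] < p) ++shift;
          if (pos[evict[i]] < first_dirty) first_dirty = pos[evict[i]];
          pos[evict[i]] = -1;
          add_to_notS(evict[i]);
        }
        std::vector<int> ns;
        ns.reserve(seq.size() - evict.size());
        for (size_t i = 0; i < seq.size(); ++i)
          if (!is_ev[seq[i]]) ns.push_back(seq[i]);
        seq.swap(ns);
        p -= shift;
      }
      seq.insert(seq.begin() + p, v);
      remove_from_notS(v);
      if (first_dirty > p) first_dirty = p;
      for (size_t i = (size_t)first_dirty; i < seq.size(); ++i)
        pos[seq[i]] = (int)i;
      if ((int)seq.size() > best_size) {
        best_size = (int)seq.size();
        std::fill(bestS.begin(), bestS.end(), false);
        for (size_t i = 0; i < seq.size(); ++i) bestS[seq[i]] = true;
        improved = true;
        if (best_size == n_elig) break;
      }
    }
    if (improved) stagnation = 0; else ++stagnation;
    temp *= cooling;
  }

  LogicalVector res(n);
  for (int v = 0; v < n; ++v) res[v] = bestS[v];
  return res;
}

// Per-column max absolute difference between two equal-shaped matrices;
// used by the batched signal-flow iteration to test convergence.
// [[Rcpp::export]]
NumericVector col_max_abs_diff_cpp(NumericMatrix a, NumericMatrix b) {
  int nr = a.nrow(), nc = a.ncol();
  NumericVector res(nc);
  for (int j = 0; j < nc; ++j) {
    double mx = 0.0;
    for (int i = 0; i < nr; ++i) {
      double d = std::abs(a(i, j) - b(i, j));
      if (d > mx) mx = d;
    }
    res[j] = mx;
  }
  return res;
}
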