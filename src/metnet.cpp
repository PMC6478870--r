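// Bipartite metabolite/reaction graph kernels: reaction-count BFS
// distances, degree-preserving double-edge swaps, and the randomized-null
// distance curve.
#include <Rcpp.h>
#include <queue>
#include <set>
using namespace Rcpp;

typedef std::vector<std::vector<int> > adj_t;

static adj_t build_adj(const IntegerVector& a, const IntegerVector& b,
                       int n) {
  adj_t adj(n);
  for (int k = 0; k < a.size(); ++k) adj[a[k]].push_back(b[k]);
  return adj;
}

// BFS from a set of source reactions; distance to a metabolite is the
// number of reaction nodes on the shortest alternating path, so a
// metabolite of a source reaction has distance 1. Unreachable: NA.
static void bfs_dist(const adj_t& met_adj, const adj_t& rxn_adj,
                     const std::vector<int>& sources,
                     std::vector<int>& mdist) {
  int n_met = met_adj.size(), n_rxn = rxn_adj.size();
  std::vector<int> rdist(n_rxn, 0);
  std::fill(mdist.begin(), mdist.end(), 0);
  std::queue<int> q;
  for (size_t i = 0; i < sources.size(); ++i) {
    int r = sources[i];
    if (r >= 0 && r < n_rxn && rdist[r] == 0) { rdist[r] = 1; q.push(r); }
  }
  while (!q.empty()) {
    int r = q.front(); q.pop();
    const std::vector<int>& ms = rxn_adj[r];
    for (size_t i = 0; i < ms.size(); ++i) {
      int m = ms[i];
      if (mdist[m] == 0) {
        mdist[m] = rdist[r];
        const std::vector<int>& rs = met_adj[m];
        for (size_t j = 0; j < rs.size(); ++j) {
          int r2 = rs[j];
          if (rdist[r2] == 0) { rdist[r2] = rdist[r] + 1; q.push(r2); }
        }
      }
    }
  }
  (void)n_met;
}

// edge arrays are 0-based: edge k joins met_id[k] -- rxn_id[k].
// sources_list: per query, 0-based reaction indices.
// [[Rcpp::export]]
IntegerMatrix bfs_distance_cpp(IntegerVector met_id, IntegerVector rxn_id,
                               int n_met, int n_rxn, List sources_list) {
  adj_t met_adj = build_adj(met_id, rxn_id, n_met);
  adj_t rxn_adj = build_adj(rxn_id, met_id, n_rxn);
  int nq = sources_list.size();
  IntegerMatrix out(nq, n_met);
  std::vector<int> mdist(n_met);
  for (int q = 0; q < nq; ++q) {
    IntegerVector s = sources_list[q];
    std::vector<int> src(s.begin(), s.end());
    bfs_dist(met_adj, rxn_adj, src, mdist);
    for (int m = 0; m < n_met; ++m)
      out(q, m) = mdist[m] == 0 ? NA_INTEGER : mdist[m];
  }
  return out;
}

// Degree-preserving randomization: n_attempts double-edge swaps
// (met_a--rxn_a, met_b--rxn_b) -> (met_a--rxn_b, met_b--rxn_a), skipping
// swaps that would duplicate an existing edge. Both degree sequences are
// preserved exactly. Uses R's RNG.
static void swap_edges(std::vector<int>& me, std::vector<int>& re,
                       int n_attempts) {
  int E = me.size();
  if (E < 2) return;
  std::set<std::pair<int, int> > edges;
  for (int k = 0; k < E; ++k)
    edges.insert(std::make_pair(me[k], re[k]));
  for (int a = 0; a < n_attempts; ++a) {
    int i = (int)(unif_rand() * E), j = (int)(unif_rand() * E);
    if (i == j) continue;
    if (me[i] == me[j] || re[i] == re[j]) continue;
    std::pair<int, int> n1(me[i], re[j]), n2(me[j], re[i]);
    if (edges.count(n1) || edges.count(n2)) continue;
    edges.erase(std::make_pair(me[i], re[i]));
    edges.erase(std::make_pair(me[j], re[j]));
    int tmp = re[i]; re[i] = re[j]; re[j] = tmp;
    edges.insert(n1);
    edges.insert(n2);
  }
}

// [[Rcpp::export]]
List swap_edges_cpp(IntegerVector met_id, IntegerVector rxn_id,
                    int n_attempts) {
  std::vector<int> me(met_id.begin(), met_id.end());
  std::vector<int> re(rxn_id.begin(), rxn_id.end());
  GetRNGstate();
  swap_edges(me, re, n_attempts);
  PutRNGstate();
  return List::create(Named("met_id") = IntegerVector(me.begin(), me.end()),
                      Named("rxn_id") = IntegerVector(re.begin(), re.end()));
}

// Null band for the distance-vs-correlation curve: for each of n_random
// degree-preserving randomizations, recompute the TR x metabolite distance
// matrix and the mean distance over the pair set selected at each
// threshold (pair_sets: per threshold, 0-based indices into the flattened
// nq x n_met distance matrix, column-major over metabolites within TR
// rows, i.e. idx = q * n_met + m). Unreachable pairs are excluded.
// [[Rcpp::export]]
NumericMatrix null_distance_curve_cpp(IntegerVector met_id,
                                      IntegerVector rxn_id,
                                      int n_met, int n_rxn,
                                      List sources_list, List pair_sets,
                                      int n_random, int swap_mult) {
  int nq = sources_list.size(), nt = pair_sets.size();
  int E = met_id.size();
  NumericMatrix out(n_random, nt);
  std::vector<std::vector<int> > srcs(nq);
  for (int q = 0; q < nq; ++q) {
    IntegerVector s = sources_list[q];
    srcs[q] = std::vector<int>(s.begin(), s.end());
  }
  std::vector<std::vector<int> > pairs(nt);
  for (int t = 0; t < nt; ++t) {
    IntegerVector p = pair_sets[t];
    pairs[t] = std::vector<int>(p.begin(), p.end());
  }
  GetRNGstate();
  std::vector<int> dist_flat(nq * n_met);
  std::vector<int> mdist(n_met);
  for (int r = 0; r < n_random; ++r) {
    std::vector<int> me(met_id.begin(), met_id.end());
    std::vector<int> re(rxn_id.begin(), rxn_id.end());
    swap_edges(me, re, swap_mult * E);
    adj_t met_adj(n_met), rxn_adj(n_rxn);
    for (int k = 0; k < E; ++k) {
      met_adj[me[k]].push_back(re[k]);
      rxn_adj[re[k]].push_back(me[k]);
    }
    for (int q = 0; q < nq; ++q) {
      bfs_dist(met_adj, rxn_adj, srcs[q], mdist);
      for (int m = 0; m < n_met; ++m)
        dist_flat[q * n_met + m] = mdist[m];
    }
    for (int t = 0; t < nt; ++t) {
      double s = 0; int n = 0;
      for (size_t k = 0; k < pairs[t].size(); ++k) {
        int d = dist_flat[pairs[t][k]];
        if (d > 0) { s += d; ++n; }
      }
      out(r, t) = n > 0 ? s / n : NA_REAL;
    }
  }
  PutRNGstate();
  return out;
}
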