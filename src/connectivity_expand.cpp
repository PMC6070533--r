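#include <Rcpp.h>
#include <unordered_map>
using namespace Rcpp;

// Iterative connectivity-significance expansion (DIAMOnD step rule).
//
// CSR adjacency: adj_ptr (length n+1) and adj_idx hold 0-based neighbor
// lists. At every iteration each non-member node with links into the
// module is scored by the upper hypergeometric tail
// P(X >= ks | degree k, module size s0, network size n); the smallest p
// wins. Ties: random draw when tie_random (uses R's RNG), otherwise the
// highest degree and then the smallest tie_rank (lexicographic name
// rank). p-values are cached per (ks, k) combination within an iteration.
// [[Rcpp::export]]
List connectivity_expand_cpp(IntegerVector adj_ptr, IntegerVector adj_idx,
                             IntegerVector deg, IntegerVector seeds,
                             int n_iter, bool tie_random,
                             IntegerVector tie_rank) {
  const int n = deg.size();
  std::vector<char> member(n, 0);
  std::vector<int> links(n, 0);
  int s0 = 0;
  for (int i = 0; i < seeds.size(); ++i) {
    const int s = seeds[i];
    if (!member[s]) { member[s] = 1; ++s0; }
  }
  for (int i = 0; i < seeds.size(); ++i) {
    const int s = seeds[i];
    for (int e = adj_ptr[s]; e < adj_ptr[s + 1]; ++e) ++links[adj_idx[e]];
  }

  std::vector<int> added;
  std::vector<double> pvals;
  added.reserve(n_iter);
  pvals.reserve(n_iter);
  std::vector<int> ties;

  for (int it = 0; it < n_iter; ++it) {
    std::unordered_map<long long, double> cache;
    double pmin = 2.0;
    ties.clear();
    for (int v = 0; v < n; ++v) {
      if (member[v] || links[v] == 0) continue;
      const long long key = (long long)links[v] * (n + 1) + deg[v];
      double p;
      auto hit = cache.find(key);
      if (hit != cache.end()) {
        p = hit->second;
      } else {
        p = R::phyper(links[v] - 1.0, (double)s0, (double)(n - s0),
                      (double)deg[v], 0, 0);
        cache[key] = p;
      }
      if (p < pmin) {
        pmin = p;
        ties.clear();
        ties.push_back(v);
      } else if (p == pmin) {
        ties.push_back(v);
      }
    }
    if (ties.empty()) break;   // boundary exhausted
    int pick;
    if (ties.size() == 1) {
      pick = ties[0];
    } else if (tie_random) {
      pick = ties[(int)(unif_rand() * ties.size())];
    } else {
      pick = ties[0];
      for (size_t t = 1; t < ties.size(); ++t) {
        const int v = ties[t];
        if (deg[v] > deg[pick] ||
            (deg[v] == deg[pick] && tie_rank[v] < tie_rank[pick])) pick = v;
      }
    }
    added.push_back(pick);
    pvals.push_back(pmin);
    member[pick] = 1;
    ++s0;
    for (int e = adj_ptr[pick]; e < adj_ptr[pick + 1]; ++e)
      ++links[adj_idx[e]];
    if (it % 32 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["added"] = wrap(added), _["p"] = wrap(pvals));
}
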