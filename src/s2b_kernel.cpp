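#include <Rcpp.h>
using namespace Rcpp;

// S2B scoring kernel.
//
// Da, Db: hop-distance matrices from every a-seed (rows) / b-seed (rows) to
// every network node (columns, -1 = unreachable). b_idx holds the 0-based
// column index of each b-seed. A seed pair (i in a, j in b) is retained when
// d(i,j) is finite and <= avgd. For a retained pair, node k lies on a
// shortest i-j path iff d(i,k) + d(k,j) == d(i,j). The summation limits of
// the score exclude pairs with j == k, which is handled by subtracting, for
// each node k that is itself a b-seed, the retained pairs ending at k (for
// which the additivity identity holds trivially).
// [[Rcpp::export]]
NumericVector s2b_kernel(IntegerMatrix Da, IntegerMatrix Db,
                         IntegerVector b_idx, double avgd) {
  const int na = Da.nrow(), nb = Db.nrow(), n = Da.ncol();
  if (Db.ncol() != n) stop("distance matrices disagree on node count");
  std::vector<double> numer(n, 0.0), cntj(n, 0.0);
  double total = 0.0;
  for (int q = 0; q < na; ++q) {
    for (int r = 0; r < nb; ++r) {
      const int dij = Da(q, b_idx[r]);
      if (dij < 0 || (double)dij > avgd) continue;
      total += 1.0;
      cntj[b_idx[r]] += 1.0;
      for (int k = 0; k < n; ++k) {
        const int d1 = Da(q, k);
        if (d1 < 0 || d1 > dij) continue;
        const int d2 = Db(r, k);
        if (d2 >= 0 && d1 + d2 == dij) numer[k] += 1.0;
      }
    }
    Rcpp::checkUserInterrupt();
  }
  NumericVector score(n);
  for (int k = 0; k < n; ++k) {
    const double den = total - cntj[k];
    score[k] = den > 0 ? (numer[k] - cntj[k]) / den : 0.0;
  }
  return score;
}
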