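#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Greedy LD pruning over a list of records already ordered for processing.
// ord: 1-based processing order of records (ascending p, ties by variant id).
// chrom: 1-based chromosome index per record's variant.
// col: 1-based column of the variant in its chromosome's r2 matrix.
// r2_by_chrom: list of square r2 matrices, one per chromosome index.
// A record is kept unless its variant exceeds the r2 threshold with a
// *different* already-kept variant on the same chromosome; records of an
// already-kept variant are always kept (same signal, another gene).
// [[Rcpp::export]]
LogicalVector greedy_ld_prune(IntegerVector ord, IntegerVector chrom,
                              IntegerVector col, List r2_by_chrom,
                              double threshold) {
  int n = ord.size();
  LogicalVector keep(n, false);
  int nc = r2_by_chrom.size();
  std::vector<NumericMatrix> mats;
  mats.reserve(nc);
  for (int c = 0; c < nc; ++c) mats.push_back(as<NumericMatrix>(r2_by_chrom[c]));
  std::vector< std::vector<int> > kept(nc);

  for (int k = 0; k < n; ++k) {
    int i = ord[k] - 1;
    int c = chrom[i] - 1;
    int v = col[i] - 1;
    bool blocked = false, already = false;
    NumericMatrix &M = mats[c];
    for (size_t u = 0; u < kept[c].size(); ++u) {
      int w = kept[c][u];
      if (w == v) { already = true; blocked = false; break; }
      if (M(v, w) > threshold) blocked = true;
    }
    if (!blocked) {
      keep[i] = true;
      if (!already) kept[c].push_back(v);
    }
  }
  return keep;
}
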