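#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Binned derived-pair counts for one sample on one chromosome.
//
// calls: 0/1/NA pseudo-haploid calls at panel sites, position-sorted.
// gpos_mM: genetic positions in milliMorgans (non-decreasing).
// edges: strictly increasing bin edges in mM; an (ordered) pair with
//   distance in [edges[b], edges[b+1]) lands in bin b; distances
//   outside the edge span are ignored.
//
// Counting is exact over all pairs: for every called site i, the set
// of called sites j > i falling into distance bin b is a contiguous
// index range (positions are sorted), so per-bin pair and
// derived-pair counts come from prefix sums over called/derived
// indicators, with one rolling pointer per bin edge. Total cost is
// O(n_sites * n_bins), which makes subsampling caps unnecessary.
//
// Returns a (nbins x 2) matrix: column 0 the number of pairs with
// both sites called, column 1 how many of those carry the derived
// allele at both sites.
// [[Rcpp::export]]
NumericMatrix pair_bin_counts(IntegerVector calls, NumericVector gpos_mM,
                              NumericVector edges) {
  const int nb = edges.size() - 1;
  if (nb < 1) stop("need at least two bin edges");
  NumericMatrix out(nb, 2);

  // compact to called sites
  std::vector<double> g;
  std::vector<int> v;
  g.reserve(calls.size());
  v.reserve(calls.size());
  for (int i = 0; i < calls.size(); ++i) {
    if (calls[i] != NA_INTEGER) {
      g.push_back(gpos_mM[i]);
      v.push_back(calls[i]);
    }
  }
  const int n = g.size();
  if (n < 2) return out;

  // prefix sums: der[k] = number of derived calls among the first k
  std::vector<double> der(n + 1, 0.0);
  for (int k = 0; k < n; ++k) der[k + 1] = der[k] + (v[k] == 1);

  // ptr[e]: first index j with g[j] - g[i] >= edges[e]; non-decreasing
  // in i, so each pointer only moves forward
  std::vector<int> ptr(nb + 1, 0);
  for (int i = 0; i < n - 1; ++i) {
    for (int e = 0; e <= nb; ++e) {
      int p = ptr[e] > i + 1 ? ptr[e] : i + 1;
      const double lim = g[i] + edges[e];
      while (p < n && g[p] < lim) ++p;
      ptr[e] = p;
    }
    const bool di = v[i] == 1;
    for (int b = 0; b < nb; ++b) {
      int lo = ptr[b] > i + 1 ? ptr[b] : i + 1;
      int hi = ptr[b + 1] > i + 1 ? ptr[b + 1] : i + 1;
      if (hi <= lo) continue;
      out(b, 0) += hi - lo;
      if (di) out(b, 1) += der[hi] - der[lo];
    }
  }
  return out;
}
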