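#include <Rcpp.h>
using namespace Rcpp;

// Gamete sampling along a marker sequence.
//
// `rec[m]` is the probability of switching the source haplotype between
// marker m-1 and marker m.  The first marker of every chromosome carries
// rec = 0.5, which (starting from an arbitrary state) makes the source
// haplotype uniform there — chromosomes therefore segregate independently
// without explicit chromosome bookkeeping in the inner loop.
//
// Driven by R's RNG (unif_rand) so set.seed() governs reproducibility.

// [[Rcpp::export]]
IntegerMatrix cpp_gametes(const IntegerMatrix& hap_a,
                          const IntegerMatrix& hap_b,
                          const IntegerVector& parent,
                          const NumericVector& rec) {
  const int n = parent.size();
  const int m = rec.size();
  if (hap_a.ncol() != m || hap_b.ncol() != m)
    stop("haplotype matrices and recombination vector disagree on marker count");
  IntegerMatrix out(n, m);
  for (int g = 0; g < n; ++g) {
    const int p = parent[g];
    if (p < 0 || p >= hap_a.nrow()) stop("parent index out of range");
    int cur = 0;
    for (int j = 0; j < m; ++j) {
      if (unif_rand() < rec[j]) cur = 1 - cur;
      out(g, j) = cur == 0 ? hap_a(p, j) : hap_b(p, j);
    }
  }
  return out;
}

// Mosaic haplotypes descending from a small set of ancestral haplotypes:
// walk markers, switching to a uniformly chosen ancestor with probability
// `sw[m]` (sw = 1 at chromosome starts).  Used by the founder generator.

// [[Rcpp::export]]
IntegerMatrix cpp_mosaic(const IntegerMatrix& ancestors,
                         const int n,
                         const NumericVector& sw) {
  const int k = ancestors.nrow();
  const int m = sw.size();
  if (ancestors.ncol() != m)
    stop("ancestor matrix and switch vector disagree on marker count");
  IntegerMatrix out(n, m);
  for (int g = 0; g < n; ++g) {
    int cur = (int)(unif_rand() * k);
    if (cur == k) cur = k - 1;
    for (int j = 0; j < m; ++j) {
      if (unif_rand() < sw[j]) {
        cur = (int)(unif_rand() * k);
        if (cur == k) cur = k - 1;
      }
      out(g, j) = ancestors(cur, j);
    }
  }
  return out;
}
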