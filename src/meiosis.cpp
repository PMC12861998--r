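#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Gamete dropping under the Haldane model: per chromosome the crossover count
// is Poisson(length / 100 cM), crossover positions are uniform, and the gamete
// alternates between the two parental haplotypes at each crossover (no
// interference). The starting haplotype is a fair coin. Uses R's RNG so that
// set.seed() upstream makes results reproducible.
//
// hap:       2n x L allele matrix (rows 2i-1, 2i are individual i)
// first_row: 1-based row of haplotype 1 of the parent of each gamete
// pos:       chromosome-local locus positions (cM), map order
// chr_first: 1-based first locus column of each chromosome
// chr_nloci: loci per chromosome
// chr_len:   chromosome lengths (cM)
// [[Rcpp::export]]
IntegerMatrix cpp_gametes(const IntegerMatrix hap, const IntegerVector first_row,
                          const NumericVector pos, const IntegerVector chr_first,
                          const IntegerVector chr_nloci, const NumericVector chr_len) {
  const int n = first_row.size();
  const int L = hap.ncol();
  const int C = chr_first.size();
  IntegerMatrix out(n, L);
  std::vector<double> xo;

  for (int g = 0; g < n; ++g) {
    const int r0 = first_row[g] - 1;
    if (r0 < 0 || r0 + 1 >= hap.nrow())
      stop("parent haplotype row out of range");
    for (int c = 0; c < C; ++c) {
      const int s = chr_first[c] - 1;
      const int m = chr_nloci[c];
      const double len = chr_len[c];
      int cur = (unif_rand() < 0.5) ? 0 : 1;
      const int nxo = (int) R::rpois(len / 100.0);
      if (nxo == 0) {
        for (int j = 0; j < m; ++j) out(g, s + j) = hap(r0 + cur, s + j);
      } else {
        xo.resize(nxo);
        for (int k = 0; k < nxo; ++k) xo[k] = unif_rand() * len;
        std::sort(xo.begin(), xo.end());
        int k = 0;
        for (int j = 0; j < m; ++j) {
          const double pj = pos[s + j];
          while (k < nxo && xo[k] <= pj) { cur = 1 - cur; ++k; }
          out(g, s + j) = hap(r0 + cur, s + j);
        }
      }
    }
  }
  return out;
}
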