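// Meiosis for the breeding-program simulator. Parents are fully homozygous
// lines, so an F1 carries one haplotype from each parent; a doubled haploid
// is a single recombinant gamete of that F1, doubled. Chromosomes are 1
// Morgan with uniformly spaced loci; crossovers are Poisson(1) per meiosis
// per chromosome, no interference. Uses R's RNG.
#include <Rcpp.h>
using namespace Rcpp;

// h1, h2: parental haplotypes (0/1 integer vectors, length n_chrom * loci
// per chromosome, chromosome-major). Returns n x L matrix of DH haplotypes.
// [[Rcpp::export]]
IntegerMatrix dh_gametes_cpp(const IntegerVector& h1, const IntegerVector& h2,
                             int n, int n_chrom, int loci_per_chrom) {
  const int L = n_chrom * loci_per_chrom;
  if (h1.size() != L || h2.size() != L)
    stop("haplotype length must equal n_chrom * loci_per_chrom");
  IntegerMatrix out(n, L);
  std::vector<double> xo;
  for (int i = 0; i < n; ++i) {
    for (int c = 0; c < n_chrom; ++c) {
      const int off = c * loci_per_chrom;
      int k = (int)R::rpois(1.0);
      xo.clear();
      for (int t = 0; t < k; ++t) xo.push_back(unif_rand());
      std::sort(xo.begin(), xo.end());
      int phase = (unif_rand() < 0.5) ? 0 : 1;
      int xi = 0;
      for (int j = 0; j < loci_per_chrom; ++j) {
        const double pos = (j + 0.5) / loci_per_chrom;  // map position in M
        while (xi < (int)xo.size() && xo[xi] < pos) {
          phase = 1 - phase;
          ++xi;
        }
        out(i, off + j) = phase == 0 ? h1[off + j] : h2[off + j];
      }
    }
  }
  return out;
}
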