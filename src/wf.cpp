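#include <Rcpp.h>
using namespace Rcpp;

// One Wright-Fisher generation on a single chromosome.
// H1/H2: current haplotypes (individuals x sites, 0/1 derived-allele codes).
// p1/p2: 0-based parent indices for each offspring (p1 == p2 for selfing).
// rec: per-interval recombination probability between adjacent sites.
// Gametes start on a random parental haplotype and switch at crossovers.
// Uses R's RNG, so results are reproducible under set.seed().

static inline void make_gamete(const IntegerMatrix& H1, const IntegerMatrix& H2,
                               int parent, int row, double rec,
                               IntegerMatrix& out) {
  const int L = H1.ncol();
  int state = unif_rand() < 0.5 ? 0 : 1;
  for (int l = 0; l < L; ++l) {
    if (l > 0 && unif_rand() < rec) state = 1 - state;
    out(row, l) = state == 0 ? H1(parent, l) : H2(parent, l);
  }
}

// [[Rcpp::export(name = ".wf_generation")]]
List wf_generation(IntegerMatrix H1, IntegerMatrix H2,
                   IntegerVector p1, IntegerVector p2, double rec) {
  const int N = p1.size(), L = H1.ncol();
  IntegerMatrix G1(N, L), G2(N, L);
  RNGScope scope;
  for (int i = 0; i < N; ++i) {
    make_gamete(H1, H2, p1[i], i, rec, G1);
    make_gamete(H1, H2, p2[i], i, rec, G2);
  }
  return List::create(_["H1"] = G1, _["H2"] = G2);
}
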