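#include <Rcpp.h>
#include <string>

using namespace Rcpp;

static inline char complementBase(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 'N';
  }
}

static inline char mutateBase(char c) {
  static const char bases[4] = {'A', 'C', 'G', 'T'};
  int cur;
  switch (c) {
    case 'A': cur = 0; break;
    case 'C': cur = 1; break;
    case 'G': cur = 2; break;
    case 'T': cur = 3; break;
    default:  return 'N';
  }
  int off = 1 + (int)(unif_rand() * 3.0);
  if (off > 3) off = 3;
  return bases[(cur + off) % 4];
}

// Draw n_pairs fragments uniformly from a random haplotype each, emit the
// two 150-bp-style mates (mate 2 reverse-complemented) with i.i.d.
// substitution errors. Uses R's RNG stream, so results are reproducible
// under set.seed().
// [[Rcpp::export]]
List cpp_simulate_reads(std::string hapA, std::string hapB, int n_pairs,
                        int read_len, int insert_size, double error_rate) {
  R_xlen_t L = (R_xlen_t)hapA.size();
  if ((R_xlen_t)hapB.size() != L) stop("haplotypes differ in length");
  if (L < insert_size) stop("genome shorter than insert size");
  CharacterVector seq1(n_pairs), seq2(n_pairs);
  IntegerVector start(n_pairs), hap(n_pairs);
  std::string r1(read_len, 'N'), r2(read_len, 'N');
  R_xlen_t span = L - insert_size + 1;
  for (int i = 0; i < n_pairs; ++i) {
    int h = unif_rand() < 0.5 ? 1 : 2;
    R_xlen_t s0 = (R_xlen_t)(unif_rand() * span);
    if (s0 >= span) s0 = span - 1;
    const std::string &g = h == 1 ? hapA : hapB;
    for (int j = 0; j < read_len; ++j) r1[j] = g[s0 + j];
    R_xlen_t m2 = s0 + insert_size - read_len;  // mate 2 on reverse strand
    for (int j = 0; j < read_len; ++j)
      r2[j] = complementBase(g[m2 + read_len - 1 - j]);
    if (error_rate > 0) {
      for (int j = 0; j < read_len; ++j) {
        if (unif_rand() < error_rate) r1[j] = mutateBase(r1[j]);
        if (unif_rand() < error_rate) r2[j] = mutateBase(r2[j]);
      }
    }
    seq1[i] = r1;
    seq2[i] = r2;
    start[i] = (int)(s0 + 1);
    hap[i] = h;
  }
  return List::create(_["seq1"] = seq1, _["seq2"] = seq2,
                      _["start"] = start, _["hap"] = hap);
}
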