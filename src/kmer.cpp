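#include <Rcpp.h>
#include <unordered_map>
#include <map>
#include <cstdint>

using namespace Rcpp;

// Canonical k-mer hash map: 2-bit packed codes, k <= 31 so a k-mer fits in
// 62 bits of a uint64_t.
typedef std::unordered_map<uint64_t, uint32_t> KmerMap;

static inline int baseCode(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

static void addSequence(KmerMap &m, const char *s, R_xlen_t n, int k) {
  uint64_t fwd = 0, rev = 0;
  const uint64_t mask = (1ULL << (2 * k)) - 1;
  const int shift = 2 * (k - 1);
  int filled = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    int c = baseCode(s[i]);
    if (c < 0) { filled = 0; fwd = 0; rev = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)c) & mask;
    rev = (rev >> 2) | ((uint64_t)(3 - c) << shift);
    if (++filled >= k) {
      uint64_t canon = fwd < rev ? fwd : rev;
      ++m[canon];
    }
  }
}

// [[Rcpp::export]]
SEXP cpp_kmer_index(CharacterVector seqs, int k) {
  if (k < 1 || k > 31) stop("k must be in [1, 31]");
  KmerMap *m = new KmerMap();
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    SEXP el = STRING_ELT(seqs, i);
    if (el == NA_STRING) continue;
    addSequence(*m, CHAR(el), LENGTH(el), k);
  }
  XPtr<KmerMap> ptr(m, true);
  return ptr;
}

// [[Rcpp::export]]
double cpp_kmer_index_size(SEXP ptr) {
  XPtr<KmerMap> p(ptr);
  return (double)p->size();
}

// [[Rcpp::export]]
List cpp_kmer_histogram(SEXP ptr) {
  XPtr<KmerMap> p(ptr);
  std::map<uint32_t, double> h;
  for (KmerMap::const_iterator it = p->begin(); it != p->end(); ++it)
    h[it->second] += 1.0;
  IntegerVector depth(h.size());
  NumericVector species(h.size());
  R_xlen_t i = 0;
  for (std::map<uint32_t, double>::const_iterator it = h.begin();
       it != h.end(); ++it, ++i) {
    depth[i] = (int)it->first;
    species[i] = it->second;
  }
  return List::create(_["depth"] = depth, _["species"] = species);
}

// Per-window canonical k-mer counts of `seq` looked up in the index;
// windows containing non-ACGT characters are NA.
// [[Rcpp::export]]
NumericVector cpp_kmer_query(SEXP ptr, std::string seq, int k) {
  XPtr<KmerMap> p(ptr);
  R_xlen_t n = (R_xlen_t)seq.size();
  R_xlen_t nwin = n >= k ? n - k + 1 : 0;
  NumericVector out(nwin, NA_REAL);
  uint64_t fwd = 0, rev = 0;
  const uint64_t mask = (1ULL << (2 * k)) - 1;
  const int shift = 2 * (k - 1);
  int filled = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    int c = baseCode(seq[i]);
    if (c < 0) { filled = 0; fwd = 0; rev = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)c) & mask;
    rev = (rev >> 2) | ((uint64_t)(3 - c) << shift);
    if (++filled >= k) {
      uint64_t canon = fwd < rev ? fwd : rev;
      KmerMap::const_iterator it = p->find(canon);
      out[i - k + 1] = it == p->end() ? 0.0 : (double)it->second;
    }
  }
  return out;
}
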