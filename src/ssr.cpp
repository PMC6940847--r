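#include <Rcpp.h>
#include <string>
#include <vector>

using namespace Rcpp;

static inline bool validBase(char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

// true if motif's minimal period equals its length (not a power of a
// shorter unit)
static bool isPrimitive(const std::string &motif) {
  int u = (int)motif.size();
  for (int d = 1; d < u; ++d) {
    if (u % d != 0) continue;
    bool periodic = true;
    for (int i = d; i < u && periodic; ++i)
      if (motif[i] != motif[i - d]) periodic = false;
    if (periodic) return false;
  }
  return true;
}

// Maximal perfect tandem runs of unit length 1..6 meeting per-unit-length
// minimum repeat numbers. Trailing partial units are truncated; motifs that
// are powers of a shorter unit are left to the shorter unit's scan.
// Coordinates 1-based inclusive.
// [[Rcpp::export]]
List cpp_find_ssrs(std::string seq, IntegerVector min_reps) {
  if (min_reps.size() != 6) stop("min_reps must have length 6");
  R_xlen_t n = (R_xlen_t)seq.size();
  std::vector<int> start, end, unit_len, reps;
  std::vector<std::string> motif;
  for (int u = 1; u <= 6; ++u) {
    R_xlen_t i = 0;
    while (i + u < n) {
      if (!validBase(seq[i]) || !validBase(seq[i + u]) ||
          seq[i] != seq[i + u]) { ++i; continue; }
      // maximal stretch of positions j with seq[j] == seq[j + u]
      R_xlen_t a = i;
      R_xlen_t j = i;
      while (j + u < n && validBase(seq[j]) && validBase(seq[j + u]) &&
             seq[j] == seq[j + u]) ++j;
      R_xlen_t span = (j - 1 + u) - a + 1;  // bases a .. j-1+u
      int r = (int)(span / u);
      if (r >= min_reps[u - 1]) {
        std::string m = seq.substr(a, u);
        if (isPrimitive(m)) {
          start.push_back((int)a + 1);
          end.push_back((int)(a + (R_xlen_t)r * u));
          unit_len.push_back(u);
          reps.push_back(r);
          motif.push_back(m);
        }
      }
      i = j + 1;  // position j failed; next run can start at j + 1
    }
  }
  return List::create(_["start"] = wrap(start), _["end"] = wrap(end),
                      _["motif"] = wrap(motif),
                      _["unit_length"] = wrap(unit_len),
                      _["repeat_number"] = wrap(reps));
}
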