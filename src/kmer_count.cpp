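#include <Rcpp.h>
#include <unordered_map>
#include <cstdint>
using namespace Rcpp;

// Canonical k-mer counting with 2-bit encoding (K <= 31).  K-mers
// containing non-ACGT symbols are skipped; each k-mer is collapsed with its
// reverse complement (lexicographically smaller encoding kept) because
// sequencing reads are unstranded.

static inline int base2bits(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

// [[Rcpp::export(name = ".kmer_spectrum_cpp")]]
List kmer_spectrum_cpp(CharacterVector reads, int K) {
  if (K < 1 || K > 31) stop("K must be in 1..31");
  std::unordered_map<uint64_t, uint32_t> table;
  table.reserve(1 << 20);
  const uint64_t mask = (K == 32) ? ~0ULL : ((1ULL << (2 * K)) - 1);
  double total_instances = 0.0;
  for (R_xlen_t r = 0; r < reads.size(); ++r) {
    const char *s = CHAR(STRING_ELT(reads, r));
    int len = LENGTH(STRING_ELT(reads, r));
    uint64_t fwd = 0, rev = 0;
    int run = 0;  // valid consecutive bases accumulated
    for (int i = 0; i < len; ++i) {
      int b = base2bits(s[i]);
      if (b < 0) { run = 0; fwd = rev = 0; continue; }
      fwd = ((fwd << 2) | (uint64_t)b) & mask;
      rev = (rev >> 2) | ((uint64_t)(3 - b) << (2 * (K - 1)));
      if (++run >= K) {
        uint64_t canon = fwd < rev ? fwd : rev;
        ++table[canon];
        total_instances += 1.0;
      }
    }
  }
  // multiplicity histogram
  std::unordered_map<uint32_t, double> hist;
  for (const auto &kv : table) hist[kv.second] += 1.0;
  IntegerVector mult(hist.size());
  NumericVector cnt(hist.size());
  R_xlen_t i = 0;
  for (const auto &kv : hist) {
    mult[i] = (int)kv.first;
    cnt[i] = kv.second;
    ++i;
  }
  return List::create(_["multiplicity"] = mult, _["count"] = cnt,
                      _["distinct"] = (double)table.size(),
                      _["total_instances"] = total_instances);
}
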