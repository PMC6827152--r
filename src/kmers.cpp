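#include <Rcpp.h>
#include <unordered_map>
#include <cstdint>
#include <cstring>
using namespace Rcpp;

// 2-bit base codes; -1 for anything that is not A/C/G/T.
static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

// Exact canonical k-mer counting over a set of reads.
// Each N-free window contributes one instance of min(window, revcomp)
// under the 2-bit encoding (A<C<G<T, matching lexicographic order).
// Codes fit exactly in a double for k <= 26 (4^26 < 2^53).
// [[Rcpp::export]]
List kmer_count_cpp(CharacterVector reads, int k) {
  if (k < 1 || k > 26) stop("k must be between 1 and 26");
  std::unordered_map<uint64_t, uint32_t> tab;
  const uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
  const int shift = 2 * (k - 1);
  for (R_xlen_t r = 0; r < reads.size(); ++r) {
    const char* s = CHAR(STRING_ELT(reads, r));
    const size_t len = std::strlen(s);
    uint64_t fwd = 0, rev = 0;
    int run = 0;
    for (size_t i = 0; i < len; ++i) {
      int c = base_code(s[i]);
      if (c < 0) { run = 0; fwd = 0; rev = 0; continue; }
      fwd = ((fwd << 2) | (uint64_t)c) & mask;
      rev = (rev >> 2) | ((uint64_t)(3 - c) << shift);
      if (++run >= k) {
        uint64_t canon = fwd < rev ? fwd : rev;
        ++tab[canon];
      }
    }
  }
  R_xlen_t n = (R_xlen_t)tab.size();
  NumericVector code(n);
  IntegerVector count(n);
  R_xlen_t i = 0;
  for (const auto& kv : tab) {
    code[i] = (double)kv.first;
    count[i] = (int)kv.second;
    ++i;
  }
  return List::create(_["code"] = code, _["count"] = count);
}

// Canonical k-mer code at every window start of one sequence.
// Windows containing a non-ACGT character yield NA.
// [[Rcpp::export]]
NumericVector kmer_codes_cpp(std::string seq, int k) {
  if (k < 1 || k > 26) stop("k must be between 1 and 26");
  const size_t len = seq.size();
  if (len < (size_t)k) return NumericVector(0);
  NumericVector out(len - k + 1, NA_REAL);
  const uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
  const int shift = 2 * (k - 1);
  uint64_t fwd = 0, rev = 0;
  int run = 0;
  for (size_t i = 0; i < len; ++i) {
    int c = base_code(seq[i]);
    if (c < 0) { run = 0; fwd = 0; rev = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)c) & mask;
    rev = (rev >> 2) | ((uint64_t)(3 - c) << shift);
    if (++run >= k) {
      uint64_t canon = fwd < rev ? fwd : rev;
      out[i - k + 1] = (double)canon;
    }
  }
  return out;
}

// Decode a canonical k-mer code back to its sequence (for inspection).
// [[Rcpp::export]]
CharacterVector kmer_decode_cpp(NumericVector codes, int k) {
  static const char bases[] = "ACGT";
  CharacterVector out(codes.size());
  std::string buf(k, 'A');
  for (R_xlen_t i = 0; i < codes.size(); ++i) {
    if (NumericVector::is_na(codes[i])) { out[i] = NA_STRING; continue; }
    uint64_t code = (uint64_t)codes[i];
    for (int j = k - 1; j >= 0; --j) {
      buf[j] = bases[code & 3ULL];
      code >>= 2;
    }
    out[i] = buf;
  }
  return out;
}
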