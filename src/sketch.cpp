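// Bottom-s MinHash sketching of canonical k-mers.
//
// Hashing uses the splitmix64 finaliser (Steele et al.) on the 2-bit k-mer
// code, truncated to the top 53 bits so every hash value is exactly
// representable as an R double; selection, set semantics and the Jaccard
// estimate all operate on these values, so the truncation is internally
// consistent and platform independent.

#include <Rcpp.h>
#include <set>
#include <cstdint>

static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

// 2-bit encoding: A=0, C=1, G=2, T=3 (order matches lexicographic order,
// so min(code_fwd, code_rc) is the canonical k-mer). Returns -1 for
// ambiguous bases.
static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

// [[Rcpp::export(name = ".sketch_hashes")]]
Rcpp::NumericVector sketch_hashes(Rcpp::CharacterVector sequences, int k,
                                  int s) {
  if (k < 1 || k > 32) Rcpp::stop("k must be in [1, 32]");
  if (s < 1) Rcpp::stop("sketch size s must be >= 1");
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);
  const int rc_shift = 2 * (k - 1);
  std::set<uint64_t> bottom;  // smallest distinct hashes, capped at s
  for (R_xlen_t i = 0; i < sequences.size(); ++i) {
    const char *seq = CHAR(STRING_ELT(sequences, i));
    uint64_t fwd = 0, rc = 0;
    int valid = 0;  // length of current run of unambiguous bases
    for (const char *p = seq; *p; ++p) {
      int c = base_code(*p);
      if (c < 0) { valid = 0; fwd = 0; rc = 0; continue; }
      fwd = ((fwd << 2) | (uint64_t)c) & mask;
      rc = (rc >> 2) | ((uint64_t)(3 - c) << rc_shift);
      if (++valid < k) continue;
      uint64_t canon = fwd < rc ? fwd : rc;
      uint64_t h = splitmix64(canon) >> 11;  // top 53 bits
      if ((int)bottom.size() < s) {
        bottom.insert(h);
      } else if (h < *bottom.rbegin()) {
        bottom.insert(h);
        if ((int)bottom.size() > s) bottom.erase(std::prev(bottom.end()));
      }
    }
  }
  Rcpp::NumericVector out(bottom.size());
  R_xlen_t j = 0;
  for (uint64_t h : bottom) out[j++] = (double)h;
  return out;  // ascending by construction
}

// Exact k-mer-set Jaccard between two sequence sets (oracle for small
// genomes; not for production-scale inputs).
// [[Rcpp::export(name = ".kmer_jaccard_exact")]]
double kmer_jaccard_exact(Rcpp::CharacterVector a, Rcpp::CharacterVector b,
                          int k) {
  if (k < 1 || k > 32) Rcpp::stop("k must be in [1, 32]");
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);
  const int rc_shift = 2 * (k - 1);
  auto collect = [&](Rcpp::CharacterVector seqs) {
    std::set<uint64_t> kmers;
    for (R_xlen_t i = 0; i < seqs.size(); ++i) {
      const char *seq = CHAR(STRING_ELT(seqs, i));
      uint64_t fwd = 0, rc = 0;
      int valid = 0;
      for (const char *p = seq; *p; ++p) {
        int c = base_code(*p);
        if (c < 0) { valid = 0; fwd = 0; rc = 0; continue; }
        fwd = ((fwd << 2) | (uint64_t)c) & mask;
        rc = (rc >> 2) | ((uint64_t)(3 - c) << rc_shift);
        if (++valid >= k) kmers.insert(fwd < rc ? fwd : rc);
      }
    }
    return kmers;
  };
  std::set<uint64_t> ka = collect(a), kb = collect(b);
  if (ka.empty() && kb.empty()) Rcpp::stop("no valid k-mers in either input");
  size_t inter = 0;
  for (uint64_t x : ka) inter += kb.count(x);
  size_t uni = ka.size() + kb.size() - inter;
  return (double)inter / (double)uni;
}
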