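#ifndef ISOQC_KMER_COMMON_H
#define ISOQC_KMER_COMMON_H

#include <cstdint>
#include <string>

// 2-bit base codes; anything not ACGT (upper case) is invalid and breaks a k-mer.
inline int base_code(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return -1;
  }
}

inline char code_base(int b) {
  static const char B[4] = {'A', 'C', 'G', 'T'};
  return B[b & 3];
}

inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 'N';
  }
}

inline std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) c = comp_base(c);
  return r;
}

// splitmix64: fixed, platform-independent 64-bit mixer used for sketch hashing.
inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

// Rolling k-mer scanner over one sequence: calls f(pos, fwd, canon) for every
// position whose window is free of non-ACGT characters. fwd is the forward-strand
// packed k-mer, canon the strand-minimum of fwd and its reverse complement.
template <typename F>
void for_each_kmer(const std::string& s, int k, F f) {
  const uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1ULL) : ~0ULL;
  uint64_t fwd = 0, rev = 0;
  int run = 0;
  const int shift = 2 * (k - 1);
  for (size_t i = 0; i < s.size(); ++i) {
    int b = base_code(s[i]);
    if (b < 0) { run = 0; fwd = 0; rev = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)b) & mask;
    rev = (rev >> 2) | ((uint64_t)(3 - b) << shift);
    if (++run >= k) {
      uint64_t canon = fwd < rev ? fwd : rev;
      f((long)(i + 1 - k), fwd, canon);
    }
  }
}

#endif
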