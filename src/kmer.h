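#pragma once

#include <string>
#include <vector>
#include <cstdint>
#include <algorithm>

// k-mer occurrence multiset stored as a sorted vector of 2-bit-packed
// codes (duplicates kept, one entry per window). Windows containing any
// non-ACGT base are skipped, so the total can be lower than L - k + 1.

typedef std::vector<uint32_t> KmerCodes;

inline int base_code(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default: return -1;
  }
}

inline KmerCodes kmer_codes_of(const std::string& s, int k) {
  KmerCodes codes;
  const int L = (int)s.size();
  if (k < 1 || k > 15 || L < k) return codes;
  codes.reserve(L - k + 1);
  const uint32_t mask = (1u << (2 * k)) - 1u;
  uint32_t cur = 0;
  int valid = 0; // length of current run of ACGT bases ending here
  for (int i = 0; i < L; ++i) {
    int c = base_code(s[i]);
    if (c < 0) { valid = 0; cur = 0; continue; }
    cur = ((cur << 2) | (uint32_t)c) & mask;
    if (++valid >= k) codes.push_back(cur);
  }
  std::sort(codes.begin(), codes.end());
  return codes;
}

// multiset intersection size == sum_tau min(n_i(tau), n_j(tau))
inline int kmer_shared_count(const KmerCodes& a, const KmerCodes& b) {
  int shared = 0;
  size_t i = 0, j = 0;
  const size_t na = a.size(), nb = b.size();
  while (i < na && j < nb) {
    if (a[i] < b[j]) ++i;
    else if (b[j] < a[i]) ++j;
    else { ++shared; ++i; ++j; }
  }
  return shared;
}

// sum_tau min(n_i, n_j) / (min(l_i, l_j) - k + 1); 0 if either sequence
// is shorter than k.
inline double kmer_sim_codes(const KmerCodes& a, int la, const KmerCodes& b,
                             int lb, int k) {
  int lmin = la < lb ? la : lb;
  if (lmin < k) return 0.0;
  return (double)kmer_shared_count(a, b) / (double)(lmin - k + 1);
}
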