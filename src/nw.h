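#pragma once

#include <string>
#include <vector>
#include <cstdint>
#include <cstdlib>
#include <algorithm>

// Global alignment with unit mismatch and unit (linear) gap costs, match 0.
// The common prefix and suffix (over non-N exact matches) are stripped
// before the DP — this preserves the optimal cost (Levenshtein property)
// and makes near-duplicate comparisons cheap — and re-attached as match
// columns. Traceback tie-break inside the stripped core: diagonal >
// gap-in-j (consume base of i) > gap-in-i, fixed so that identity is a
// deterministic function of the input pair. 'N' never matches anything,
// including 'N'.

struct AlnStats {
  int cost;
  int matches;
  int mismatches;
  int gap_cols;
};

static const int NW_INF = 1 << 28;

inline int nw_sub(char a, char b) {
  return (a == b && a != 'N') ? 0 : 1;
}

// longest common prefix/suffix of non-N matches; p + s <= min(n, m)
inline void nw_affix(const std::string& a, const std::string& b, int& p,
                     int& s) {
  const int n = (int)a.size(), m = (int)b.size();
  const int lim = n < m ? n : m;
  p = 0;
  while (p < lim && a[p] == b[p] && a[p] != 'N') ++p;
  s = 0;
  while (s < lim - p && a[n - 1 - s] == b[m - 1 - s] && a[n - 1 - s] != 'N')
    ++s;
}

// Fills D ((n+1) x (m+1), row-major) for the full strings (no stripping)
// and returns the optimal cost. band <= 0 means unbanded; otherwise cells
// with |i - j| > half-width are INF, half-width = max(band, |n - m|) so
// the corner stays reachable.
inline int nw_fill(const std::string& a, const std::string& b, int band,
                   std::vector<int>& D) {
  const int n = (int)a.size(), m = (int)b.size();
  const int W = m + 1;
  if (band > 0) {
    D.assign((size_t)(n + 1) * W, NW_INF);
    int hw = band;
    int d = n > m ? n - m : m - n;
    if (hw < d) hw = d;
    D[0] = 0;
    for (int j = 1; j <= m && j <= hw; ++j) D[j] = j;
    for (int i = 1; i <= n; ++i) {
      int jlo = i - hw; if (jlo < 0) jlo = 0;
      int jhi = i + hw; if (jhi > m) jhi = m;
      if (jlo == 0) D[(size_t)i * W] = i;
      const char ai = a[i - 1];
      const int* up = &D[(size_t)(i - 1) * W];
      int* cur = &D[(size_t)i * W];
      for (int j = (jlo > 0 ? jlo : 1); j <= jhi; ++j) {
        int best = up[j - 1] + nw_sub(ai, b[j - 1]);
        int v = up[j] + 1;
        if (v < best) best = v;
        v = cur[j - 1] + 1;
        if (v < best) best = v;
        cur[j] = best;
      }
    }
    return D[(size_t)n * W + m];
  }
  D.resize((size_t)(n + 1) * W);
  for (int j = 0; j <= m; ++j) D[j] = j;
  const char* bp = b.data();
  for (int i = 1; i <= n; ++i) {
    const char ai = a[i - 1];
    const int* up = &D[(size_t)(i - 1) * W];
    int* cur = &D[(size_t)i * W];
    int left = i;
    cur[0] = i;
    for (int j = 1; j <= m; ++j) {
      int v = up[j - 1] + ((ai == bp[j - 1] && ai != 'N') ? 0 : 1);
      const int u = up[j] + 1;
      if (u < v) v = u;
      const int l = left + 1;
      if (l < v) v = l;
      cur[j] = v;
      left = v;
    }
  }
  return D[(size_t)n * W + m];
}

// Traceback statistics over a filled core matrix (strings as passed to
// nw_fill).
inline AlnStats nw_stats_from(const std::string& a, const std::string& b,
                              const std::vector<int>& D) {
  const int n = (int)a.size(), m = (int)b.size();
  const int W = m + 1;
  AlnStats s;
  s.cost = D[(size_t)n * W + m];
  s.matches = s.mismatches = s.gap_cols = 0;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    const int cur = D[(size_t)i * W + j];
    if (i > 0 && j > 0) {
      int sub = nw_sub(a[i - 1], b[j - 1]);
      if (D[(size_t)(i - 1) * W + (j - 1)] + sub == cur) {
        if (sub == 0) ++s.matches; else ++s.mismatches;
        --i; --j;
        continue;
      }
    }
    if (i > 0 && D[(size_t)(i - 1) * W + j] + 1 == cur) {
      ++s.gap_cols; --i;
    } else {
      ++s.gap_cols; --j;
    }
  }
  return s;
}

// Full-pair stats with affix stripping; D is a reusable scratch buffer.
// The pair is canonicalised (lexicographically smaller sequence first)
// before the DP so that every column statistic — and hence the
// gap-ignoring identity — is symmetric in the two sequences; all stats
// are invariant under transposing the alignment.
inline AlnStats nw_pair_stats(const std::string& a, const std::string& b,
                              int band, std::vector<int>& D) {
  if (b.compare(a) < 0) return nw_pair_stats(b, a, band, D);
  int p, s;
  nw_affix(a, b, p, s);
  const int n = (int)a.size(), m = (int)b.size();
  AlnStats st;
  if (p + s == n && p + s == m) {
    st.cost = 0; st.matches = n; st.mismatches = 0; st.gap_cols = 0;
    return st;
  }
  const std::string ca = a.substr(p, n - p - s);
  const std::string cb = b.substr(p, m - p - s);
  if (ca.empty() || cb.empty()) {
    st.cost = (int)(ca.size() + cb.size());
    st.matches = p + s;
    st.mismatches = 0;
    st.gap_cols = st.cost;
    return st;
  }
  nw_fill(ca, cb, band, D);
  st = nw_stats_from(ca, cb, D);
  st.matches += p + s;
  return st;
}

inline double identity_from_stats(const AlnStats& s) {
  const int denom = s.matches + s.mismatches;
  return denom > 0 ? (double)s.matches / denom : 0.0;
}

inline double nw_identity_buf(const std::string& a, const std::string& b,
                              int band, std::vector<int>& D) {
  return identity_from_stats(nw_pair_stats(a, b, band, D));
}
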