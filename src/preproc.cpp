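#include <Rcpp.h>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

// Sliding-window quality truncation. Window length w = max(1,
// round-half-up(window_frac * L)); windows slide 5'->3' in steps of one; at
// the first window whose mean quality drops below `thr` the read is cut at
// the first sub-threshold base inside that window. Returns the kept length
// per read. Qualities are Phred+33 characters.
// [[Rcpp::export]]
IntegerVector qtrim_len_cpp(CharacterVector quals, double thr,
                            double window_frac) {
  IntegerVector out(quals.size());
  for (R_xlen_t r = 0; r < quals.size(); ++r) {
    if (quals[r] == NA_STRING) { out[r] = NA_INTEGER; continue; }
    std::string q = as<std::string>(quals[r]);
    const int L = (int)q.size();
    if (L == 0) { out[r] = 0; continue; }
    int w = (int)std::floor(window_frac * L + 0.5);
    if (w < 1) w = 1;
    if (w > L) w = L;
    int keep = L;
    long sum = 0;
    for (int i = 0; i < w; ++i) sum += q[i] - 33;
    for (int s = 0; s + w <= L; ++s) {
      if (s > 0) sum += (q[s + w - 1] - 33) - (q[s - 1] - 33);
      if ((double)sum / w < thr) {
        for (int t = s; t < s + w; ++t) {
          if ((double)(q[t] - 33) < thr) { keep = t; break; }
        }
        break;
      }
    }
    out[r] = keep;
  }
  return out;
}

// IUPAC nucleotide bitmasks (A=1, C=2, G=4, T=8). Used for primer
// positions: primer N matches any base.
static int iupac_mask(char c) {
  switch (c) {
    case 'A': return 1; case 'C': return 2; case 'G': return 4;
    case 'T': return 8; case 'U': return 8;
    case 'R': return 1 | 4; case 'Y': return 2 | 8; case 'S': return 2 | 4;
    case 'W': return 1 | 8; case 'K': return 4 | 8; case 'M': return 1 | 2;
    case 'B': return 2 | 4 | 8; case 'D': return 1 | 4 | 8;
    case 'H': return 1 | 2 | 8; case 'V': return 1 | 2 | 4;
    case 'N': return 15;
    default: return 0;
  }
}

// Read-side base mask: an unknown base (N) in the read matches nothing,
// so primers are never located inside uncalled stretches; other IUPAC
// letters in the read match by set intersection.
static int read_mask(char c) {
  return c == 'N' ? 0 : iupac_mask(c);
}

// Semi-global primer location: the primer is aligned end-to-end with unit
// edit costs, read end-gaps are free. Degenerate (IUPAC) primer positions
// match at cost 0 when the base sets intersect; an N in the read matches
// no primer base. For a 5' primer returns
// c(min_errors, n_leading_bases_to_trim); the trim point is the end of the
// best match (ties broken toward the leftmost match). For a 3' primer both
// strings are reversed, so the returned cut is the number of trailing
// bases to trim.
// [[Rcpp::export]]
IntegerVector primer_locate_cpp(std::string read, std::string primer,
                                bool five_prime = true) {
  if (!five_prime) {
    std::reverse(read.begin(), read.end());
    std::reverse(primer.begin(), primer.end());
  }
  const int p = (int)primer.size(), r = (int)read.size();
  std::vector<int> prev(r + 1), cur(r + 1);
  for (int j = 0; j <= r; ++j) prev[j] = 0; // free leading read bases
  for (int i = 1; i <= p; ++i) {
    cur[0] = i;
    const int pm = iupac_mask(primer[i - 1]);
    for (int j = 1; j <= r; ++j) {
      const int rm = read_mask(read[j - 1]);
      int best = prev[j - 1] + ((pm & rm) ? 0 : 1);
      int v = prev[j] + 1;
      if (v < best) best = v;
      v = cur[j - 1] + 1;
      if (v < best) best = v;
      cur[j] = best;
    }
    prev.swap(cur);
  }
  int err = prev[0], cut = 0;
  for (int j = 1; j <= r; ++j)
    if (prev[j] < err) { err = prev[j]; cut = j; }
  return IntegerVector::create(err, cut);
}
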