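#include <Rcpp.h>
#include <algorithm>
#include "nw.h"
#include "kmer.h"

using namespace Rcpp;

// [[Rcpp::export]]
List nw_align_cpp(std::string a, std::string b, int band = 0) {
  // canonical orientation (see nw_pair_stats): align the smaller string
  // as sequence i and transpose the result, so identity is symmetric
  if (b.compare(a) < 0) {
    List sw = nw_align_cpp(b, a, band);
    return List::create(
      _["aligned_i"] = sw["aligned_j"], _["aligned_j"] = sw["aligned_i"],
      _["cost"] = sw["cost"], _["matches"] = sw["matches"],
      _["mismatches"] = sw["mismatches"],
      _["gap_columns"] = sw["gap_columns"]);
  }
  int p, s;
  nw_affix(a, b, p, s);
  const int n = (int)a.size(), m = (int)b.size();
  const std::string ca = a.substr(p, n - p - s);
  const std::string cb = b.substr(p, m - p - s);
  std::string ai = a.substr(0, p), aj = b.substr(0, p);
  int matches = p + s, mismatches = 0, gap_cols = 0, cost = 0;
  std::string mi, mj; // middle alignment, built in reverse
  if (!ca.empty() || !cb.empty()) {
    if (ca.empty() || cb.empty()) {
      // pure gap remainder
      for (size_t t = 0; t < ca.size(); ++t) { mi.push_back(ca[t]); mj.push_back('-'); }
      for (size_t t = 0; t < cb.size(); ++t) { mi.push_back('-'); mj.push_back(cb[t]); }
      gap_cols = cost = (int)(ca.size() + cb.size());
    } else {
      std::vector<int> D;
      cost = nw_fill(ca, cb, band, D);
      const int cn = (int)ca.size(), cm = (int)cb.size();
      const int W = cm + 1;
      int i = cn, j = cm;
      std::string ri, rj;
      while (i > 0 || j > 0) {
        const int cur = D[(size_t)i * W + j];
        bool done = false;
        if (i > 0 && j > 0) {
          int sub = nw_sub(ca[i - 1], cb[j - 1]);
          if (D[(size_t)(i - 1) * W + (j - 1)] + sub == cur) {
            ri.push_back(ca[i - 1]); rj.push_back(cb[j - 1]);
            if (sub == 0) ++matches; else ++mismatches;
            --i; --j; done = true;
          }
        }
        if (!done) {
          if (i > 0 && D[(size_t)(i - 1) * W + j] + 1 == cur) {
            ri.push_back(ca[i - 1]); rj.push_back('-');
            ++gap_cols; --i;
          } else {
            ri.push_back('-'); rj.push_back(cb[j - 1]);
            ++gap_cols; --j;
          }
        }
      }
      std::reverse(ri.begin(), ri.end());
      std::reverse(rj.begin(), rj.end());
      mi = ri; mj = rj;
    }
  }
  ai += mi; aj += mj;
  ai += a.substr(n - s); aj += b.substr(m - s);
  return List::create(
    _["aligned_i"] = ai, _["aligned_j"] = aj, _["cost"] = cost,
    _["matches"] = matches, _["mismatches"] = mismatches,
    _["gap_columns"] = gap_cols);
}

// [[Rcpp::export]]
double nw_identity_cpp(std::string a, std::string b, int band = 0) {
  std::vector<int> D;
  return nw_identity_buf(a, b, band, D);
}

// [[Rcpp::export]]
double kmer_similarity_cpp(std::string a, std::string b, int k) {
  KmerCodes p = kmer_codes_of(a, k), q = kmer_codes_of(b, k);
  return kmer_sim_codes(p, (int)a.size(), q, (int)b.size(), k);
}

// k-mer similarity of one query against many sequences.
// [[Rcpp::export]]
NumericVector kmer_sim_many_cpp(std::string query, CharacterVector db, int k) {
  KmerCodes qp = kmer_codes_of(query, k);
  const int lq = (int)query.size();
  NumericVector out(db.size());
  for (R_xlen_t i = 0; i < db.size(); ++i) {
    std::string s = as<std::string>(db[i]);
    KmerCodes sp = kmer_codes_of(s, k);
    out[i] = kmer_sim_codes(qp, lq, sp, (int)s.size(), k);
  }
  return out;
}

// Per-query-position alignment column classes against one parent:
// 2 = match column, 1 = mismatch column, 0 = query base aligned to a gap
// (column ignored by gap-ignoring identity). Parent-gap-consuming columns
// do not map to a query position and are dropped.
void query_match_profile_into(const std::string& query,
                              const std::string& parent, int band,
                              std::vector<int>& D, int* out) {
  int p, s;
  nw_affix(query, parent, p, s);
  const int n = (int)query.size(), m = (int)parent.size();
  for (int t = 0; t < p; ++t) out[t] = 2;
  for (int t = n - s; t < n; ++t) out[t] = 2;
  const std::string cq = query.substr(p, n - p - s);
  const std::string cp = parent.substr(p, m - p - s);
  if (cq.empty()) return;
  if (cp.empty()) {
    for (int t = p; t < n - s; ++t) out[t] = 0;
    return;
  }
  nw_fill(cq, cp, band, D);
  const int cn = (int)cq.size(), cm = (int)cp.size();
  const int W = cm + 1;
  int i = cn, j = cm;
  while (i > 0 || j > 0) {
    const int cur = D[(size_t)i * W + j];
    bool done = false;
    if (i > 0 && j > 0) {
      int sub = nw_sub(cq[i - 1], cp[j - 1]);
      if (D[(size_t)(i - 1) * W + (j - 1)] + sub == cur) {
        out[p + i - 1] = sub == 0 ? 2 : 1;
        --i; --j; done = true;
      }
    }
    if (!done) {
      if (i > 0 && D[(size_t)(i - 1) * W + j] + 1 == cur) {
        out[p + i - 1] = 0; --i;
      } else {
        --j;
      }
    }
  }
}

// [[Rcpp::export]]
IntegerVector query_match_profile_cpp(std::string query, std::string parent,
                                      int band = 0) {
  IntegerVector out((int)query.size());
  std::vector<int> D;
  query_match_profile_into(query, parent, band, D, out.begin());
  return out;
}
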