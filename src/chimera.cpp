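#include <Rcpp.h>
#include <algorithm>
#include "nw.h"
#include "kmer.h"

using namespace Rcpp;

void query_match_profile_into(const std::string& query,
                              const std::string& parent, int band,
                              std::vector<int>& D, int* out);

// Two-parent chimera scan over a dereplicated set given in canonical order
// (abundance desc). Queries are processed in increasing abundance order;
// flagged queries are excluded as parents for later queries. Per query the
// candidate parents (abundance >= fold x query, unflagged) are pruned to the
// `max_parents` best k-mer similarities, aligned once each, and all ordered
// parent pairs x breakpoints are scored from cumulative match /
// gapless-column counts projected onto query coordinates.
// [[Rcpp::export]]
List chimera_scan_cpp(CharacterVector seqs, IntegerVector abund,
                      double min_model_identity, double min_gain,
                      double min_parent_fold, int max_parents, int k,
                      int band = 0) {
  const int n = (int)seqs.size();
  std::vector<std::string> sq(n);
  std::vector<int> len(n);
  std::vector<KmerCodes> prof(n);
  for (int i = 0; i < n; ++i) {
    sq[i] = as<std::string>(seqs[i]);
    len[i] = (int)sq[i].size();
    prof[i] = kmer_codes_of(sq[i], k);
  }
  std::vector<char> flagged(n, 0);
  LogicalVector is_chim(n, false);
  IntegerVector pa(n, NA_INTEGER), pb(n, NA_INTEGER), bp(n, NA_INTEGER);
  NumericVector model_id(n, NA_REAL), best_single(n, NA_REAL);
  std::vector<int> D;
  std::vector<int> profbuf;
  std::vector<double> cm, cg; // cumulative, (max_parents) x (L+1)

  for (int q = n - 1; q >= 0; --q) {
    const int L = len[q];
    if (L < 2) continue;
    std::vector<int> cand;
    for (int i = 0; i < n; ++i) {
      if (i == q || flagged[i]) continue;
      if ((double)abund[i] >= min_parent_fold * (double)abund[q])
        cand.push_back(i);
    }
    if ((int)cand.size() < 2) continue;
    std::vector<double> sim(cand.size());
    for (size_t t = 0; t < cand.size(); ++t)
      sim[t] = kmer_sim_codes(prof[q], L, prof[cand[t]], len[cand[t]], k);
    std::vector<int> ord(cand.size());
    for (size_t t = 0; t < ord.size(); ++t) ord[t] = (int)t;
    const int P = std::min((int)cand.size(), max_parents);
    std::partial_sort(ord.begin(), ord.begin() + P, ord.end(),
                      [&](int x, int y) {
      if (sim[x] != sim[y]) return sim[x] > sim[y];
      int a = cand[x], b = cand[y];
      if (abund[a] != abund[b]) return abund[a] > abund[b];
      if (len[a] != len[b]) return len[a] > len[b];
      int c = sq[a].compare(sq[b]);
      if (c != 0) return c < 0;
      return a < b;
    });
    std::vector<int> par(P);
    for (int t = 0; t < P; ++t) par[t] = cand[ord[t]];

    profbuf.assign(L, 0);
    cm.assign((size_t)P * (L + 1), 0.0);
    cg.assign((size_t)P * (L + 1), 0.0);
    for (int t = 0; t < P; ++t) {
      query_match_profile_into(sq[q], sq[par[t]], band, D, profbuf.data());
      double* M = &cm[(size_t)t * (L + 1)];
      double* G = &cg[(size_t)t * (L + 1)];
      M[0] = G[0] = 0;
      for (int x = 0; x < L; ++x) {
        M[x + 1] = M[x] + (profbuf[x] == 2 ? 1 : 0);
        G[x + 1] = G[x] + (profbuf[x] != 0 ? 1 : 0);
      }
      profbuf.assign(L, 0);
    }
    double bs = 0;
    for (int t = 0; t < P; ++t) {
      double tg = cg[(size_t)t * (L + 1) + L];
      double id = tg > 0 ? cm[(size_t)t * (L + 1) + L] / tg : 0;
      if (id > bs) bs = id;
    }
    double best_id = -1;
    int best_a = -1, best_b = -1, best_bp = -1;
    for (int a = 0; a < P; ++a) {
      const double* Ma = &cm[(size_t)a * (L + 1)];
      const double* Ga = &cg[(size_t)a * (L + 1)];
      for (int b = 0; b < P; ++b) {
        if (a == b) continue;
        const double* Mb = &cm[(size_t)b * (L + 1)];
        const double* Gb = &cg[(size_t)b * (L + 1)];
        const double tmb = Mb[L], tgb = Gb[L];
        for (int x = 1; x < L; ++x) {
          const double den = Ga[x] + (tgb - Gb[x]);
          if (den <= 0) continue;
          const double id = (Ma[x] + (tmb - Mb[x])) / den;
          if (id > best_id) {
            best_id = id; best_a = a; best_b = b; best_bp = x;
          }
        }
      }
    }
    best_single[q] = bs;
    if (best_id >= 0) model_id[q] = best_id;
    if (best_id >= min_model_identity && best_id - bs >= min_gain) {
      is_chim[q] = true;
      flagged[q] = 1;
      pa[q] = par[best_a] + 1;
      pb[q] = par[best_b] + 1;
      bp[q] = best_bp;
    }
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["is_chimera"] = is_chim, _["parent_a"] = pa,
                      _["parent_b"] = pb, _["breakpoint"] = bp,
                      _["model_identity"] = model_id,
                      _["best_single_identity"] = best_single);
}
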