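#include <Rcpp.h>
#include <algorithm>
#include "nw.h"
#include "kmer.h"

using namespace Rcpp;

// Greedy abundance-seeded clustering.
//
// Inputs must already be in seed-priority order (abundance desc, length desc,
// sequence ascending byte order): index 0 is the first seed. For each seed the
// remaining pool is ranked by decreasing k-mer similarity (ties: abundance
// desc, length desc, sequence asc, index asc) and scanned; a target is
// accepted when its gap-ignoring pairwise identity to the seed is >= s_thr.
// Accepts reset the reject counter, rejects increment it; the scan stops once
// n_rej > m (m may be +Inf). Candidates are drawn lazily from a binary heap,
// which realises exactly the sorted-scan semantics without paying for a full
// sort when the reject counter stops the scan early.

namespace {

struct Db {
  std::vector<std::string> seq;
  std::vector<int> abund;
  std::vector<int> len;
  std::vector<KmerCodes> codes;
};

void build_db(const CharacterVector& seqs, const IntegerVector& abund, int k,
              Db& db) {
  const int n = (int)seqs.size();
  db.seq.resize(n); db.abund.resize(n); db.len.resize(n); db.codes.resize(n);
  for (int i = 0; i < n; ++i) {
    db.seq[i] = as<std::string>(seqs[i]);
    db.abund[i] = abund[i];
    db.len[i] = (int)db.seq[i].size();
    db.codes[i] = kmer_codes_of(db.seq[i], k);
  }
}

// scan-order comparator: true when x ranks before y
struct RankBefore {
  const Db& db;
  const std::vector<double>& sim;
  bool operator()(int x, int y) const {
    if (sim[x] != sim[y]) return sim[x] > sim[y];
    if (db.abund[x] != db.abund[y]) return db.abund[x] > db.abund[y];
    if (db.len[x] != db.len[y]) return db.len[x] > db.len[y];
    int c = db.seq[x].compare(db.seq[y]);
    if (c != 0) return c < 0;
    return x < y;
  }
};

// scan candidates for one seed, drawing them best-first from a heap;
// returns accepted indices in scan order. sim[] must be filled for all
// entries of cand.
std::vector<int> scan_heap(int seed, std::vector<int>& cand, const Db& db,
                           const std::vector<double>& sim, double s_thr,
                           double m, int band, std::vector<int>& buf) {
  RankBefore before{db, sim};
  auto heap_cmp = [&](int x, int y) { return before(y, x); }; // max-heap
  std::make_heap(cand.begin(), cand.end(), heap_cmp);
  std::vector<int> acc;
  double n_rej = 0;
  size_t live = cand.size();
  while (live > 0) {
    if (n_rej > m) break;
    std::pop_heap(cand.begin(), cand.begin() + live, heap_cmp);
    const int t = cand[--live];
    double id = nw_identity_buf(db.seq[seed], db.seq[t], band, buf);
    if (id >= s_thr) { acc.push_back(t); n_rej = 0; }
    else ++n_rej;
  }
  return acc;
}

} // namespace

// [[Rcpp::export]]
List cluster_greedy_cpp(CharacterVector seqs, IntegerVector abund,
                        double s_thr, double m, int k, int band = 0) {
  const int n = (int)seqs.size();
  Db db;
  build_db(seqs, abund, k, db);
  std::vector<int> buf;
  std::vector<char> assigned(n, 0);
  IntegerVector assignment(n, NA_INTEGER);
  std::vector<int> centroids;
  std::vector<std::vector<int> > members;
  std::vector<int> active;
  active.reserve(n);
  for (int i = 0; i < n; ++i) active.push_back(i);
  std::vector<double> sim(n, 0.0);

  // Inverted k-mer index (k <= 8 gives at most 4^8 codes): per code the
  // (sequence, count) postings. Shared-k-mer counts for one seed are then
  // accumulated by walking the postings of the seed's distinct codes,
  // which is much cheaper than a multiset merge per candidate. Assigned
  // sequences are skipped lazily.
  const bool use_index = k <= 8;
  std::vector<std::vector<std::pair<int, int> > > postings;
  if (use_index) {
    postings.resize((size_t)1 << (2 * k));
    for (int i = 0; i < n; ++i) {
      const KmerCodes& c = db.codes[i];
      for (size_t t = 0; t < c.size();) {
        size_t u = t + 1;
        while (u < c.size() && c[u] == c[t]) ++u;
        postings[c[t]].push_back(std::make_pair(i, (int)(u - t)));
        t = u;
      }
    }
  }
  std::vector<int> shared(n, 0);
  std::vector<int> touched;
  touched.reserve(n);

  while (!active.empty()) {
    const int seed = active.front();
    std::vector<int> cand(active.begin() + 1, active.end());
    if (use_index) {
      const KmerCodes& c = db.codes[seed];
      for (size_t t = 0; t < c.size();) {
        size_t u = t + 1;
        while (u < c.size() && c[u] == c[t]) ++u;
        const int cs = (int)(u - t);
        const std::vector<std::pair<int, int> >& post = postings[c[t]];
        for (size_t e = 0; e < post.size(); ++e) {
          const int tgt = post[e].first;
          if (assigned[tgt] || tgt == seed) continue;
          if (shared[tgt] == 0) touched.push_back(tgt);
          shared[tgt] += cs < post[e].second ? cs : post[e].second;
        }
        t = u;
      }
      const int ls = db.len[seed];
      for (size_t t = 0; t < touched.size(); ++t) {
        const int tgt = touched[t];
        const int lmin = ls < db.len[tgt] ? ls : db.len[tgt];
        sim[tgt] = lmin < k ? 0.0
          : (double)shared[tgt] / (double)(lmin - k + 1);
        shared[tgt] = 0;
      }
    } else {
      for (size_t t = 0; t < cand.size(); ++t)
        sim[cand[t]] = kmer_sim_codes(db.codes[seed], db.len[seed],
                                      db.codes[cand[t]], db.len[cand[t]],
                                      k);
    }
    std::vector<int> acc = scan_heap(seed, cand, db, sim, s_thr, m, band,
                                     buf);
    if (use_index) {
      // reset sims of touched candidates for the next seed
      for (size_t t = 0; t < touched.size(); ++t) sim[touched[t]] = 0.0;
      touched.clear();
    }

    const int cid = (int)centroids.size() + 1;
    centroids.push_back(seed + 1);
    std::vector<int> mem;
    mem.push_back(seed + 1);
    assignment[seed] = cid;
    assigned[seed] = 1;
    for (size_t t = 0; t < acc.size(); ++t) {
      assignment[acc[t]] = cid;
      assigned[acc[t]] = 1;
      mem.push_back(acc[t] + 1);
    }
    members.push_back(mem);

    std::vector<int> next;
    next.reserve(active.size());
    for (size_t t = 0; t < active.size(); ++t)
      if (!assigned[active[t]]) next.push_back(active[t]);
    active.swap(next);
    Rcpp::checkUserInterrupt();
  }

  List mem_out(members.size());
  for (size_t c = 0; c < members.size(); ++c)
    mem_out[c] = IntegerVector(members[c].begin(), members[c].end());
  return List::create(_["assignment"] = assignment,
                      _["centroids"] = IntegerVector(centroids.begin(),
                                                     centroids.end()),
                      _["members"] = mem_out);
}

// Single-seed search against a database (seed itself must not be in db).
// Returns 1-based indices of accepted targets in scan order.
// [[Rcpp::export]]
IntegerVector search_cpp(std::string seed, CharacterVector seqs,
                         IntegerVector abund, double s_thr, double m, int k,
                         int band = 0) {
  Db db;
  build_db(seqs, abund, k, db);
  KmerCodes sc = kmer_codes_of(seed, k);
  const int sl = (int)seed.size();
  const int n = (int)db.seq.size();
  // stage the seed as a virtual extra entry so scan_heap can align to it
  db.seq.push_back(seed);
  db.len.push_back(sl);
  db.abund.push_back(0);
  std::vector<int> cand(n);
  std::vector<double> sim(n + 1, 0.0);
  for (int i = 0; i < n; ++i) {
    cand[i] = i;
    sim[i] = kmer_sim_codes(sc, sl, db.codes[i], db.len[i], k);
  }
  std::vector<int> buf;
  std::vector<int> acc = scan_heap(n, cand, db, sim, s_thr, m, band, buf);
  IntegerVector out(acc.size());
  for (size_t i = 0; i < acc.size(); ++i) out[i] = acc[i] + 1;
  return out;
}

// Best-hit-above-threshold reference assignment for one query: candidates
// ranked by k-mer similarity, scanned with the reject counter; among accepted
// hits the one with maximal identity wins (ties: first in scan order).
// Returns (best_index_1based_or_0, best_identity).
// [[Rcpp::export]]
NumericVector assign_best_cpp(std::string query, CharacterVector seqs,
                              IntegerVector abund, double s_thr, double m,
                              int k, int band = 0) {
  Db db;
  build_db(seqs, abund, k, db);
  KmerCodes qc = kmer_codes_of(query, k);
  const int ql = (int)query.size();
  const int n = (int)db.seq.size();
  std::vector<int> cand(n);
  std::vector<double> sim(n, 0.0);
  for (int i = 0; i < n; ++i) {
    cand[i] = i;
    sim[i] = kmer_sim_codes(qc, ql, db.codes[i], db.len[i], k);
  }
  RankBefore before{db, sim};
  std::sort(cand.begin(), cand.end(), before);
  std::vector<int> buf;
  double n_rej = 0, best_id = -1.0;
  int best = 0;
  for (int t = 0; t < n; ++t) {
    if (n_rej > m) break;
    double id = nw_identity_buf(query, db.seq[cand[t]], band, buf);
    if (id >= s_thr) {
      n_rej = 0;
      if (id > best_id) { best_id = id; best = cand[t] + 1; }
    } else ++n_rej;
  }
  return NumericVector::create(best, best_id);
}
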