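// Seeded gapless local search used by the internal iterative PSSM engine.
//
// Queries and subjects are integer-coded residues (1..20 alphabetical,
// 0 = X). Scoring is either a 20x20 substitution matrix (iteration 1) or a
// query-anchored position-specific matrix (later iterations). For every
// subject the best gapless local segment is found by Kadane's rule along
// candidate diagonals; candidates come from exact k-mer seeds against the
// query (all diagonals are scanned for small problems, so tiny fixtures
// lose no sensitivity). A hit is kept when its score passes the ungapped
// Karlin-Altschul significance threshold S >= ln(K*m*n/E) / lambda.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Segment {
  double score = -1.0;
  int qstart = 0, sstart = 0, len = 0;
};

// Kadane over one diagonal. qoff/soff are the 0-based starting offsets of
// the diagonal; n is its length. score(qi, si) is provided by a callable.
template <typename ScoreFn>
void scan_diagonal(int qoff, int soff, int n, ScoreFn score, Segment& best) {
  double run = 0.0;
  int run_start = 0;
  for (int t = 0; t < n; ++t) {
    double s = score(qoff + t, soff + t);
    if (run <= 0.0) {
      run = s;
      run_start = t;
    } else {
      run += s;
    }
    if (run > best.score) {
      // trim a (weakly) negative prefix cannot occur: run resets at <= 0
      best.score = run;
      best.qstart = qoff + run_start;
      best.sstart = soff + run_start;
      best.len = t - run_start + 1;
    }
  }
}

template <typename ScoreFn>
Segment best_segment(const IntegerVector& q, const IntegerVector& s,
                     ScoreFn score, int kmer, bool exhaustive) {
  int nq = q.size(), ns = s.size();
  Segment best;
  if (nq == 0 || ns == 0) return best;
  if (exhaustive || nq < kmer || ns < kmer ||
      (double)nq * (double)ns <= 40000.0) {
    for (int d = -(nq - 1); d <= ns - 1; ++d) {
      int qoff = d < 0 ? -d : 0;
      int soff = d < 0 ? 0 : d;
      int n = std::min(nq - qoff, ns - soff);
      scan_diagonal(qoff, soff, n, score, best);
    }
    return best;
  }
  // hash query k-mers (skip any containing X = 0)
  std::unordered_map<int, std::vector<int>> qk;
  qk.reserve(nq * 2);
  for (int i = 0; i + kmer <= nq; ++i) {
    int code = 0;
    bool ok = true;
    for (int j = 0; j < kmer; ++j) {
      if (q[i + j] == 0) { ok = false; break; }
      code = code * 21 + q[i + j];
    }
    if (ok) qk[code].push_back(i);
  }
  std::unordered_map<int, char> seen;  // diagonals already scanned
  for (int i = 0; i + kmer <= ns; ++i) {
    int code = 0;
    bool ok = true;
    for (int j = 0; j < kmer; ++j) {
      if (s[i + j] == 0) { ok = false; break; }
      code = code * 21 + s[i + j];
    }
    if (!ok) continue;
    auto it = qk.find(code);
    if (it == qk.end()) continue;
    for (int qpos : it->second) {
      int d = i - qpos;
      if (seen.count(d)) continue;
      seen[d] = 1;
      int qoff = d < 0 ? -d : 0;
      int soff = d < 0 ? 0 : d;
      int n = std::min(nq - qoff, ns - soff);
      scan_diagonal(qoff, soff, n, score, best);
    }
  }
  return best;
}

}  // namespace

// [[Rcpp::export(name = ".cpp_gapless_search")]]
DataFrame cpp_gapless_search(IntegerVector query, List subjects,
                             NumericMatrix scorer, bool positionSpecific,
                             double lambda, double K, double evalue,
                             int kmer = 3, bool exhaustive = false) {
  int nq = query.size();
  std::vector<int> idx;
  std::vector<double> scores;
  std::vector<int> qstarts, sstarts, lens;
  const double xpen = -1.0;  // score involving an X residue
  for (int si = 0; si < subjects.size(); ++si) {
    IntegerVector subj = subjects[si];
    Segment best;
    if (positionSpecific) {
      // scorer: nq x 20 position-specific log-odds
      auto fn = [&](int qi, int sj) {
        int a = subj[sj];
        if (a == 0) return xpen;
        return scorer(qi, a - 1);
      };
      best = best_segment(query, subj, fn, kmer, exhaustive);
    } else {
      auto fn = [&](int qi, int sj) {
        int a = query[qi], b = subj[sj];
        if (a == 0 || b == 0) return xpen;
        return scorer(a - 1, b - 1);
      };
      best = best_segment(query, subj, fn, kmer, exhaustive);
    }
    double smin = std::log(K * (double)nq * (double)subj.size() /
                           evalue) / lambda;
    if (best.len > 0 && best.score >= smin) {
      idx.push_back(si + 1);
      scores.push_back(best.score);
      qstarts.push_back(best.qstart);
      sstarts.push_back(best.sstart);
      lens.push_back(best.len);
    }
  }
  return DataFrame::create(_["subject"] = idx, _["score"] = scores,
                           _["qstart"] = qstarts, _["sstart"] = sstarts,
                           _["len"] = lens);
}
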