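#include <Rcpp.h>
#include <climits>
#include <vector>
#include <string>
using namespace Rcpp;

// Wraparound alignment of a genomic segment against an unbounded tandem
// concatenation of a monomer (the TRF scoring model).  Fitting alignment:
// the whole segment is consumed, entry and exit monomer columns are free,
// and after the last monomer column the alignment re-enters column 1.
//
// Rows i = 0..n index segment prefixes, columns j = 0..p-1 index the
// monomer position last consumed.  Within-row horizontal moves (monomer
// column consumed against a gap) are cyclic; because each such move costs
// a positive indel penalty, value propagation around the cycle converges
// and repeated left-to-right sweeps reach the fixed point (two sweeps
// suffice for positive penalties; we iterate until no change as a guard).
//
// dir codes: 0 start row, 1 diagonal, 2 vertical (segment base vs gap),
// 3 horizontal (monomer column vs gap, cyclic).
// [[Rcpp::export]]
List wrap_align_cpp(std::string seg, std::string mono,
                    int match, int mismatch, int indel) {
  const int n = (int) seg.size();
  const int p = (int) mono.size();
  std::vector<int> prev(p, 0), cur(p, 0);
  std::vector<unsigned char> dir((size_t)(n + 1) * p, 0);

  for (int i = 1; i <= n; ++i) {
    const char sc = seg[i - 1];
    unsigned char *drow = &dir[(size_t) i * p];
    for (int j = 0; j < p; ++j) {
      const char mc = mono[j];
      const int sub = (sc == mc && sc != 'N') ? match : -mismatch;
      int best = prev[(j == 0) ? p - 1 : j - 1] + sub;
      unsigned char d = 1;
      const int v = prev[j] - indel;
      if (v > best) { best = v; d = 2; }
      if (j > 0) {
        const int h = cur[j - 1] - indel;
        if (h > best) { best = h; d = 3; }
      }
      cur[j] = best;
      drow[j] = d;
    }
    if (p > 1) {
      for (int sweep = 0; sweep < p + 1; ++sweep) {
        bool changed = false;
        int h = cur[p - 1] - indel;
        if (h > cur[0]) { cur[0] = h; drow[0] = 3; changed = true; }
        for (int j = 1; j < p; ++j) {
          h = cur[j - 1] - indel;
          if (h > cur[j]) { cur[j] = h; drow[j] = 3; changed = true; }
        }
        if (!changed) break;
        if (indel <= 0) break;  // degenerate weights: one pass only
      }
    }
    std::swap(prev, cur);
  }

  // best end column (smallest index on ties, deterministic)
  int jbest = 0;
  for (int j = 1; j < p; ++j) if (prev[j] > prev[jbest]) jbest = j;
  const int score = prev[jbest];

  // one optimal traceback
  long matches = 0, mismatches = 0, indels = 0, consumed = 0;
  int i = n, j = jbest;
  const long long cap = (long long)(n + 2) * (p + 2);
  long long steps = 0;
  while (i > 0 && steps++ < cap) {
    const unsigned char d = dir[(size_t) i * p + j];
    if (d == 1) {
      if (seg[i - 1] == mono[j] && seg[i - 1] != 'N') ++matches;
      else ++mismatches;
      ++consumed;
      --i;
      j = (j == 0) ? p - 1 : j - 1;
    } else if (d == 2) {
      ++indels;
      --i;
    } else if (d == 3) {
      ++indels;
      ++consumed;
      j = (j == 0) ? p - 1 : j - 1;
    } else {
      break;  // start row reached mid-cell (should not happen for i > 0)
    }
  }

  return List::create(_["score"] = score,
                      _["matches"] = (double) matches,
                      _["mismatches"] = (double) mismatches,
                      _["indels"] = (double) indels,
                      _["consumed"] = (double) consumed);
}

// Global Needleman-Wunsch alignment with unit weights (+1 match, -1
// mismatch, -1 gap, end gaps penalized), maximizing (score, matches)
// lexicographically.  With these weights the column count of any
// (score, matches)-optimal alignment is determined:
//   score = M - MM - G  and  columns = M + MM + G  =>  columns = 2M - score,
// so identity = 100 * M / (2M - score) is traceback-free and symmetric.
// [[Rcpp::export]]
NumericVector nw_identity_cpp(std::string a, std::string b) {
  const int n = (int) a.size();
  const int m = (int) b.size();
  std::vector<int> ps(m + 1), cs(m + 1);   // best score
  std::vector<int> pm(m + 1), cm(m + 1);   // max matches among optimal
  for (int j = 0; j <= m; ++j) { ps[j] = -j; pm[j] = 0; }
  for (int i = 1; i <= n; ++i) {
    cs[0] = -i;
    cm[0] = 0;
    const char ac = a[i - 1];
    for (int j = 1; j <= m; ++j) {
      const bool is_match = (ac == b[j - 1] && ac != 'N');
      int bs = ps[j - 1] + (is_match ? 1 : -1);
      int bm = pm[j - 1] + (is_match ? 1 : 0);
      int s2 = ps[j] - 1, m2 = pm[j];
      if (s2 > bs || (s2 == bs && m2 > bm)) { bs = s2; bm = m2; }
      s2 = cs[j - 1] - 1; m2 = cm[j - 1];
      if (s2 > bs || (s2 == bs && m2 > bm)) { bs = s2; bm = m2; }
      cs[j] = bs;
      cm[j] = bm;
    }
    std::swap(ps, cs);
    std::swap(pm, cm);
  }
  const int score = ps[m];
  const long matches = pm[m];
  const long columns = 2 * matches - score;
  const double identity = columns > 0 ? 100.0 * matches / columns : 0.0;
  return NumericVector::create(_["identity"] = identity,
                               _["matches"] = (double) matches,
                               _["columns"] = (double) columns,
                               _["score"] = (double) score);
}
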