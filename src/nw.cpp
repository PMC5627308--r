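#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Needleman-Wunsch global alignment with match +1, mismatch 0 and linear
// gap penalty -1, tracking (score, matches, alignment length) per cell.
// Ties are resolved deterministically: maximize score, then matches, then
// prefer the shorter alignment.  X never counts as a match (ambiguity
// code), matching the R-side identity substitution matrix.

struct Cell { int s; int m; int l; };

static inline bool better(const Cell& a, const Cell& b) {
  if (a.s != b.s) return a.s > b.s;
  if (a.m != b.m) return a.m > b.m;
  return a.l < b.l;
}

static void nw_pair(const std::string& a, const std::string& b,
                    int& matches, int& length) {
  const int n = a.size(), m = b.size();
  std::vector<Cell> prev(m + 1), cur(m + 1);
  for (int j = 0; j <= m; ++j) prev[j] = {-j, 0, j};
  for (int i = 1; i <= n; ++i) {
    cur[0] = {-i, 0, i};
    for (int j = 1; j <= m; ++j) {
      const bool is_match = a[i - 1] == b[j - 1] && a[i - 1] != 'X';
      Cell diag = {prev[j - 1].s + (is_match ? 1 : 0),
                   prev[j - 1].m + (is_match ? 1 : 0), prev[j - 1].l + 1};
      Cell up   = {prev[j].s - 1, prev[j].m, prev[j].l + 1};
      Cell left = {cur[j - 1].s - 1, cur[j - 1].m, cur[j - 1].l + 1};
      Cell best = diag;
      if (better(up, best)) best = up;
      if (better(left, best)) best = left;
      cur[j] = best;
    }
    std::swap(prev, cur);
  }
  matches = prev[m].m;
  length = prev[m].l;
}

// [[Rcpp::export(name = ".nw_identity")]]
NumericVector nw_identity(CharacterVector a, std::string b) {
  const int n = a.size();
  NumericVector out(n);
  for (int k = 0; k < n; ++k) {
    int matches, length;
    nw_pair(std::string(a[k]), b, matches, length);
    out[k] = (double)matches / (double)length;
  }
  return out;
}
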