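#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Minimum Levenshtein distance from every window of `seq` to a reference
// set, for all window lengths in [w_min, w_max] at once: for a fixed
// start and reference, one DP table over the longest window yields the
// distance of every shorter window as an intermediate last-column value.
// Row i (0-based window start) and column (L - w_min) hold
// min_ref lev(seq[i..i+L-1], ref); windows running past the end are NA.
// Only the window starts in `starts` (0-based) are computed; callers
// deduplicate identical windows (tandem repeats are periodic) and expand.
// [[Rcpp::export]]
IntegerMatrix min_unit_costs(std::string seq, CharacterVector refs,
                             int w_min, int w_max, IntegerVector starts) {
  int n = (int)seq.size();
  int nL = w_max - w_min + 1;
  int ns = starts.size();
  IntegerMatrix out(ns, nL);
  std::fill(out.begin(), out.end(), NA_INTEGER);
  int m = refs.size();
  std::vector<std::string> rs(m);
  for (int j = 0; j < m; ++j) rs[j] = as<std::string>(refs[j]);
  std::vector<int> prev, cur;
  for (int si = 0; si < ns; ++si) {
    int i = starts[si];
    int maxL = std::min(w_max, n - i);
    if (maxL < w_min) continue;
    for (int r = 0; r < m; ++r) {
      const std::string& ref = rs[r];
      int lb = (int)ref.size();
      prev.resize(lb + 1);
      cur.resize(lb + 1);
      for (int j = 0; j <= lb; ++j) prev[j] = j;
      for (int a = 1; a <= maxL; ++a) {
        cur[0] = a;
        char ca = seq[i + a - 1];
        for (int j = 1; j <= lb; ++j) {
          int c = prev[j] + 1;
          int d = cur[j - 1] + 1;
          int s = prev[j - 1] + (ca != ref[j - 1] ? 1 : 0);
          if (d < c) c = d;
          if (s < c) c = s;
          cur[j] = c;
        }
        if (a >= w_min) {
          int col = a - w_min;
          int v = cur[lb];
          if (out(si, col) == NA_INTEGER || v < out(si, col))
            out(si, col) = v;
        }
        std::swap(prev, cur);
      }
    }
  }
  return out;
}
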