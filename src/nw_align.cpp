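#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment with unit costs:
// match +1, mismatch -1, gap -1 (linear). Traceback preference when tied:
// diagonal, then up (gap in b), then left (gap in a) -- fixed for determinism.
//
// Returns the quantities clustering needs: the number of identical aligned
// residues, the alignment width (gap columns included), and the number of
// aligned residue pairs (match + mismatch columns).
// [[Rcpp::export]]
List nw_align_stats(std::string a, std::string b) {
  const int n = a.size(), m = b.size();
  std::vector<int> prev(m + 1), cur(m + 1);
  // traceback matrix: 0 = diag, 1 = up, 2 = left
  std::vector<unsigned char> tb((n + 1) * (size_t)(m + 1));
  for (int j = 0; j <= m; ++j) { prev[j] = -j; tb[j] = 2; }
  tb[0] = 0;
  for (int i = 1; i <= n; ++i) {
    cur[0] = -i;
    tb[(size_t)i * (m + 1)] = 1;
    for (int j = 1; j <= m; ++j) {
      int sdiag = prev[j - 1] + (a[i - 1] == b[j - 1] ? 1 : -1);
      int sup = prev[j] - 1;
      int sleft = cur[j - 1] - 1;
      int best = sdiag; unsigned char dir = 0;
      if (sup > best) { best = sup; dir = 1; }
      if (sleft > best) { best = sleft; dir = 2; }
      cur[j] = best;
      tb[(size_t)i * (m + 1) + j] = dir;
    }
    std::swap(prev, cur);
  }
  int score = prev[m];
  // traceback
  int i = n, j = m, matches = 0, pairs = 0, width = 0;
  while (i > 0 || j > 0) {
    unsigned char dir = tb[(size_t)i * (m + 1) + j];
    ++width;
    if (dir == 0 && i > 0 && j > 0) {
      ++pairs;
      if (a[i - 1] == b[j - 1]) ++matches;
      --i; --j;
    } else if (dir == 1 && i > 0) {
      --i;
    } else {
      --j;
    }
  }
  return List::create(_["score"] = score, _["matches"] = matches,
                      _["pairs"] = pairs, _["width"] = width);
}
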