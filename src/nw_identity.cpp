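#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment with linear gap penalty and a
// deterministic traceback (diagonal > up > left on ties).  Returns the
// number of identical aligned columns, the total alignment length and the
// optimal score.  Identity = matches / alignment length.
// [[Rcpp::export(name = ".nw_align_stats")]]
NumericVector nw_align_stats(std::string a, std::string b,
                             double match = 1.0, double mismatch = -1.0,
                             double gap = -1.0) {
  const int n = a.size(), m = b.size();
  std::vector<double> prev(m + 1), cur(m + 1);
  // traceback codes: 0 diag, 1 up (gap in b), 2 left (gap in a)
  std::vector<unsigned char> tb((size_t)(n + 1) * (m + 1));
  for (int j = 0; j <= m; ++j) { prev[j] = j * gap; tb[j] = 2; }
  tb[0] = 0;
  for (int i = 1; i <= n; ++i) {
    cur[0] = i * gap;
    tb[(size_t)i * (m + 1)] = 1;
    for (int j = 1; j <= m; ++j) {
      double sdiag = prev[j - 1] + (a[i - 1] == b[j - 1] ? match : mismatch);
      double sup = prev[j] + gap;
      double sleft = cur[j - 1] + gap;
      double best = sdiag; unsigned char dir = 0;
      if (sup > best) { best = sup; dir = 1; }
      if (sleft > best) { best = sleft; dir = 2; }
      cur[j] = best;
      tb[(size_t)i * (m + 1) + j] = dir;
    }
    std::swap(prev, cur);
  }
  double score = prev[m];
  int i = n, j = m, matches = 0, cols = 0;
  while (i > 0 || j > 0) {
    unsigned char dir = tb[(size_t)i * (m + 1) + j];
    if (i > 0 && j > 0 && dir == 0) {
      if (a[i - 1] == b[j - 1]) ++matches;
      --i; --j;
    } else if (i > 0 && (dir == 1 || j == 0)) {
      --i;
    } else {
      --j;
    }
    ++cols;
  }
  return NumericVector::create(_["matches"] = matches,
                               _["columns"] = cols,
                               _["score"] = score);
}
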