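#include <Rcpp.h>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Optimal-matching edit distance between two cell sequences on the
// state-space grid. Cells are rows (u, v) of level indices; the
// substitution cost is the Manhattan distance |u1-u2| + |v1-v2|,
// insertions/deletions cost `indel`. Standard O(n*m) dynamic programme
// with a two-row band.
// [[Rcpp::export]]
double om_dist_cpp(const IntegerMatrix& s1, const IntegerMatrix& s2,
                   double indel) {
  const int n = s1.nrow(), m = s2.nrow();
  std::vector<double> prev(m + 1), cur(m + 1);
  for (int j = 0; j <= m; ++j) prev[j] = j * indel;
  for (int i = 1; i <= n; ++i) {
    cur[0] = i * indel;
    const int u1 = s1(i - 1, 0), v1 = s1(i - 1, 1);
    for (int j = 1; j <= m; ++j) {
      const double sub = std::abs(u1 - s2(j - 1, 0)) +
                         std::abs(v1 - s2(j - 1, 1));
      double d = prev[j - 1] + sub;
      d = std::min(d, prev[j] + indel);
      d = std::min(d, cur[j - 1] + indel);
      cur[j] = d;
    }
    std::swap(prev, cur);
  }
  return prev[m];
}
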