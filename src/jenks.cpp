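#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Exact Fisher-Jenks optimal 1-D partition into k classes minimising the
// total within-class sum of squared deviations.  Dynamic programme over
// sorted values with prefix sums; O(k n^2) time, O(k n) backpointers.
// Input must be sorted ascending.  Returns the 1-based index of the last
// element of each class.
// [[Rcpp::export]]
IntegerVector cpp_jenks_ends(NumericVector x, int k) {
  const int n = x.size();
  if (k < 1 || k > n) stop("invalid class count");
  std::vector<double> cs(n + 1, 0.0), cs2(n + 1, 0.0);
  for (int i = 0; i < n; ++i) {
    cs[i + 1] = cs[i] + x[i];
    cs2[i + 1] = cs2[i] + x[i] * x[i];
  }
  auto ssd = [&](int i, int j) {  // 0-based inclusive range [i, j]
    double s = cs[j + 1] - cs[i], s2 = cs2[j + 1] - cs2[i];
    int len = j - i + 1;
    return s2 - s * s / len;
  };
  const double inf = R_PosInf;
  std::vector<double> prev(n), cur(n);
  std::vector<std::vector<int>> back(k, std::vector<int>(n, 0));
  for (int j = 0; j < n; ++j) prev[j] = ssd(0, j);
  for (int m = 1; m < k; ++m) {
    for (int j = 0; j < n; ++j) {
      if (j < m) { cur[j] = inf; continue; }
      double best = inf; int arg = m;
      for (int i = m; i <= j; ++i) {  // class m starts at i
        double v = prev[i - 1] + ssd(i, j);
        if (v < best) { best = v; arg = i; }
      }
      cur[j] = best;
      back[m][j] = arg;
    }
    std::swap(prev, cur);
  }
  IntegerVector ends(k);
  int j = n - 1;
  for (int m = k - 1; m >= 1; --m) {
    ends[m] = j + 1;
    j = back[m][j] - 1;
  }
  ends[0] = j + 1;
  return ends;
}
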