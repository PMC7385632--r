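#include <Rcpp.h>
using namespace Rcpp;

// Fisher's optimal 1-D partition minimizing total within-class sum of
// squared deviations. Input must be sorted ascending. Returns the 1-based
// index of the last element of each of the k classes.
// [[Rcpp::export(name = ".fisher_jenks_cpp")]]
IntegerVector fisher_jenks_cpp(NumericVector x, int k) {
  int n = x.size();
  if (k < 1 || k > n) stop("fisher_jenks: need 1 <= k <= n");

  std::vector<double> s1(n + 1, 0.0), s2(n + 1, 0.0);
  for (int i = 0; i < n; ++i) {
    s1[i + 1] = s1[i] + x[i];
    s2[i + 1] = s2[i] + x[i] * x[i];
  }
  // ssq of x[i..j] inclusive, 0-based
  auto ssq = [&](int i, int j) {
    double sum = s1[j + 1] - s1[i];
    double sq = s2[j + 1] - s2[i];
    int m = j - i + 1;
    return sq - sum * sum / m;
  };

  // D[j][i]: minimal cost of first i+1 values in j+1 classes
  std::vector<std::vector<double>> D(k, std::vector<double>(n, 0.0));
  std::vector<std::vector<int>> B(k, std::vector<int>(n, 0));
  for (int i = 0; i < n; ++i) D[0][i] = ssq(0, i);
  for (int j = 1; j < k; ++j) {
    for (int i = j; i < n; ++i) {
      double best = R_PosInf;
      int arg = j;
      for (int t = j; t <= i; ++t) {
        double c = D[j - 1][t - 1] + ssq(t, i);
        if (c < best) { best = c; arg = t; }
      }
      D[j][i] = best;
      B[j][i] = arg;  // class j starts at index arg
    }
  }

  IntegerVector ends(k);
  int i = n - 1;
  for (int j = k - 1; j >= 1; --j) {
    ends[j] = i + 1;          // 1-based last index of class j
    i = B[j][i] - 1;          // previous class ends just before start
  }
  ends[0] = i + 1;
  return ends;
}
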