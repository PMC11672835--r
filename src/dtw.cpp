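#include <Rcpp.h>
using namespace Rcpp;

// Classic dynamic time warping: full cost matrix, L1 local cost,
// steps {(1,0),(0,1),(1,1)}, boundary-anchored path, no window constraint.
// Returns the cumulative path distance and (optionally) the optimal path.
// [[Rcpp::export(name = ".dtw_core")]]
List dtw_core(NumericVector x, NumericVector y, bool return_path) {
  const int n = x.size(), m = y.size();
  if (n == 0 || m == 0) stop("dtw: empty input sequence");
  std::vector<double> prev(m), cur(m);
  // step matrix for backtracking: 0 = diag, 1 = up (i-1), 2 = left (j-1)
  std::vector<signed char> bt;
  if (return_path) bt.resize((size_t)n * m);

  for (int j = 0; j < m; ++j) {
    double c = std::abs(x[0] - y[j]);
    prev[j] = (j == 0) ? c : prev[j - 1] + c;
    if (return_path) bt[j] = (j == 0) ? -1 : 2;
  }
  for (int i = 1; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      double c = std::abs(x[i] - y[j]);
      if (j == 0) {
        cur[0] = prev[0] + c;
        if (return_path) bt[(size_t)i * m] = 1;
      } else {
        double best = prev[j - 1];
        signed char dir = 0;
        if (prev[j] < best) { best = prev[j]; dir = 1; }
        if (cur[j - 1] < best) { best = cur[j - 1]; dir = 2; }
        cur[j] = best + c;
        if (return_path) bt[(size_t)i * m + j] = dir;
      }
    }
    std::swap(prev, cur);
  }
  double dist = prev[m - 1];
  if (!return_path) {
    return List::create(_["distance"] = dist);
  }
  std::vector<int> pi, pj;
  int i = n - 1, j = m - 1;
  while (true) {
    pi.push_back(i + 1);
    pj.push_back(j + 1);
    if (i == 0 && j == 0) break;
    signed char dir = bt[(size_t)i * m + j];
    if (dir == 0) { --i; --j; }
    else if (dir == 1) { --i; }
    else { --j; }
  }
  std::reverse(pi.begin(), pi.end());
  std::reverse(pj.begin(), pj.end());
  return List::create(_["distance"] = dist,
                      _["path"] = DataFrame::create(_["i"] = wrap(pi),
                                                    _["j"] = wrap(pj)));
}
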