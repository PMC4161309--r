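#include <Rcpp.h>
using namespace Rcpp;

// Permutation null for the gene-conversion fragment scan: maximum-segment
// (Kadane) score of a +1/-penalty sequence over n polymorphic sites of
// which m are mismatches, with mismatch positions permuted uniformly. All
// requested penalties are evaluated on the same permutations (one column
// per penalty). Uses R's RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
NumericMatrix max_segment_null_cpp(int n, int m, NumericVector penalties,
                                   int nperm) {
  int np = penalties.size();
  NumericMatrix out(nperm, np);
  std::vector<int> idx(n);
  std::vector<signed char> mis(n, 0);
  std::vector<double> cur(np), best(np);
  for (int i = 0; i < n; ++i) idx[i] = i;
  for (int b = 0; b < nperm; ++b) {
    for (int k = 0; k < m; ++k) {
      int j = k + (int)(unif_rand() * (n - k));
      if (j >= n) j = n - 1;
      std::swap(idx[k], idx[j]);
      mis[idx[k]] = 1;
    }
    for (int p = 0; p < np; ++p) { cur[p] = 0.0; best[p] = 0.0; }
    for (int i = 0; i < n; ++i) {
      if (mis[i]) {
        for (int p = 0; p < np; ++p) {
          double c = (cur[p] > 0.0 ? cur[p] : 0.0) - penalties[p];
          cur[p] = c;
          if (c > best[p]) best[p] = c;
        }
      } else {
        for (int p = 0; p < np; ++p) {
          double c = (cur[p] > 0.0 ? cur[p] : 0.0) + 1.0;
          cur[p] = c;
          if (c > best[p]) best[p] = c;
        }
      }
    }
    for (int p = 0; p < np; ++p) out(b, p) = best[p];
    for (int k = 0; k < m; ++k) mis[idx[k]] = 0;
  }
  return out;
}
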