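#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Mean over B resamples of the median of a size-k subset of `values`,
// drawn without (default) or with replacement. Uses R's RNG so results are
// reproducible under set.seed(); subsets are drawn by partial Fisher-Yates.
// [[Rcpp::export]]
double cpp_boot_median(NumericVector values, int k, int B, bool replace) {
  int n = values.size();
  if (k < 1 || (!replace && k > n)) stop("infeasible subset size");
  std::vector<double> pool(values.begin(), values.end());
  std::vector<int> idx(n);
  std::vector<double> sub(k);
  const int lo = (k - 1) / 2, hi = k / 2;  // middle order statistics
  double acc = 0.0;
  for (int b = 0; b < B; ++b) {
    if (replace) {
      for (int i = 0; i < k; ++i) {
        int j = (int)(unif_rand() * n);
        if (j == n) j = n - 1;
        sub[i] = pool[j];
      }
    } else {
      for (int i = 0; i < n; ++i) idx[i] = i;
      for (int i = 0; i < k; ++i) {
        int j = i + (int)(unif_rand() * (n - i));
        if (j >= n) j = n - 1;
        std::swap(idx[i], idx[j]);
        sub[i] = pool[idx[i]];
      }
    }
    std::nth_element(sub.begin(), sub.begin() + lo, sub.end());
    double med = sub[lo];
    if (hi != lo) {
      med = 0.5 * (med + *std::min_element(sub.begin() + lo + 1, sub.end()));
    }
    acc += med;
  }
  return acc / B;
}
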