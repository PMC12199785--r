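#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Moving median over a k-sample neighbourhood, ignoring NA values.
// For even k the window is left-biased: sample i uses indices
// [i - k/2, i + k/2 - 1]; for odd k it is centred. Windows are truncated at
// the edges. Positions that are NA on input stay NA.
// [[Rcpp::export(name = ".moving_median")]]
NumericVector moving_median(NumericVector x, int k) {
  int n = x.size();
  NumericVector out(n);
  int left = k / 2;              // extra sample goes to the left for even k
  int right = (k - 1) / 2;
  std::vector<double> buf;
  buf.reserve(k);
  for (int i = 0; i < n; ++i) {
    if (NumericVector::is_na(x[i])) { out[i] = NA_REAL; continue; }
    buf.clear();
    int lo = std::max(0, i - left);
    int hi = std::min(n - 1, i + right);
    for (int j = lo; j <= hi; ++j)
      if (!NumericVector::is_na(x[j])) buf.push_back(x[j]);
    int m = buf.size();
    std::nth_element(buf.begin(), buf.begin() + m / 2, buf.end());
    double med = buf[m / 2];
    if (m % 2 == 0) {
      double lowmid = *std::max_element(buf.begin(), buf.begin() + m / 2);
      med = (med + lowmid) / 2.0;
    }
    out[i] = med;
  }
  return out;
}
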