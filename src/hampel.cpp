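#include <Rcpp.h>
#include <algorithm>
#include <vector>

// median of a small scratch vector (sorts in place)
static double med_inplace(std::vector<double>& w) {
  const size_t n = w.size();
  std::sort(w.begin(), w.end());
  if (n % 2 == 1) return w[n / 2];
  return 0.5 * (w[n / 2 - 1] + w[n / 2]);
}

// Sliding-window Hampel filter with truncated edge windows.
// Sample i is replaced by the median of x[max(0,i-k) .. min(n-1,i+k)] when it
// deviates from that median by more than n_mad * 1.4826 * MAD of the window.
// [[Rcpp::export(name = ".hampel_core")]]
Rcpp::List hampel_core(Rcpp::NumericVector x, int k, double n_mad) {
  const int n = x.size();
  Rcpp::NumericVector out = Rcpp::clone(x);
  Rcpp::LogicalVector mask(n);
  std::vector<double> w, dev;
  w.reserve(2 * k + 1);
  dev.reserve(2 * k + 1);
  for (int i = 0; i < n; ++i) {
    const int lo = std::max(0, i - k);
    const int hi = std::min(n - 1, i + k);
    w.assign(x.begin() + lo, x.begin() + hi + 1);
    const double med = med_inplace(w);
    dev.resize(w.size());
    for (size_t j = 0; j < w.size(); ++j) dev[j] = std::abs(w[j] - med);
    const double sig = 1.4826 * med_inplace(dev);
    if (std::abs(x[i] - med) > n_mad * sig) {
      out[i] = med;
      mask[i] = true;
    }
  }
  return Rcpp::List::create(Rcpp::Named("x") = out,
                            Rcpp::Named("outliers") = mask);
}
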