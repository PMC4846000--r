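// Small numeric helpers for the synthetic-data generator.

#include <Rcpp.h>

using namespace Rcpp;

// First-order recursive filter y[t] = a*y[t-1] + x[t] (Ornstein-Uhlenbeck
// discretization used for the 1/f-type cortical background).
// [[Rcpp::export(name = ".ar1_filter")]]
NumericVector ar1_filter(NumericVector x, double a) {
  int n = x.size();
  NumericVector y(n);
  double prev = 0.0;
  for (int i = 0; i < n; ++i) {
    prev = a * prev + x[i];
    y[i] = prev;
  }
  return y;
}
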