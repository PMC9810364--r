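#include <Rcpp.h>
using namespace Rcpp;

// IIR filter, direct form II transposed, with initial conditions.
// b, a: coefficient vectors (a[0] assumed 1 after normalization in R).
// zi: length max(length(a), length(b)) - 1 initial state.
// [[Rcpp::export]]
NumericVector cpp_lfilter(NumericVector b, NumericVector a,
                          NumericVector x, NumericVector zi) {
  int nf = std::max(b.size(), a.size());
  std::vector<double> bb(nf, 0.0), aa(nf, 0.0);
  for (int i = 0; i < b.size(); ++i) bb[i] = b[i];
  for (int i = 0; i < a.size(); ++i) aa[i] = a[i];
  int n = x.size(), ns = nf - 1;
  std::vector<double> z(ns, 0.0);
  for (int i = 0; i < ns && i < zi.size(); ++i) z[i] = zi[i];
  NumericVector y(n);
  for (int t = 0; t < n; ++t) {
    double xt = x[t];
    double yt = bb[0] * xt + z[0];
    for (int k = 0; k < ns - 1; ++k)
      z[k] = bb[k + 1] * xt + z[k + 1] - aa[k + 1] * yt;
    z[ns - 1] = bb[ns] * xt - aa[ns] * yt;
    y[t] = yt;
  }
  return y;
}
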