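#include <Rcpp.h>
using namespace Rcpp;

// Direct-form II transposed IIR filter, a[0] assumed 1 (normalized upstream).
// [[Rcpp::export]]
NumericVector iir_filter_cpp(NumericVector b, NumericVector a, NumericVector x) {
  int nb = b.size(), na = a.size(), n = x.size();
  int nz = std::max(nb, na) - 1;
  std::vector<double> z(nz, 0.0), bb(nz + 1, 0.0), aa(nz + 1, 0.0);
  for (int i = 0; i < nb; ++i) bb[i] = b[i];
  for (int i = 0; i < na; ++i) aa[i] = a[i];
  NumericVector y(n);
  for (int t = 0; t < n; ++t) {
    double xt = x[t];
    double yt = bb[0] * xt + z[0];
    for (int k = 0; k < nz - 1; ++k)
      z[k] = bb[k + 1] * xt + z[k + 1] - aa[k + 1] * yt;
    if (nz > 0)
      z[nz - 1] = bb[nz] * xt - aa[nz] * yt;
    y[t] = yt;
  }
  return y;
}
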