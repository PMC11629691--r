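#include <Rcpp.h>
using namespace Rcpp;

// Direct-form-II-transposed IIR filter with initial state zi.
// a[0] is assumed 1 (coefficients normalised by the caller).
// [[Rcpp::export]]
NumericVector iir_filter_cpp(NumericVector b, NumericVector a,
                             NumericVector x, NumericVector zi) {
  int n = x.size();
  int nf = std::max(b.size(), a.size());
  std::vector<double> bb(nf, 0.0), aa(nf, 0.0), z(nf - 1, 0.0);
  for (int i = 0; i < b.size(); ++i) bb[i] = b[i];
  for (int i = 0; i < a.size(); ++i) aa[i] = a[i];
  for (int i = 0; i < (int)z.size() && i < zi.size(); ++i) z[i] = zi[i];
  NumericVector y(n);
  for (int i = 0; i < n; ++i) {
    double xi = x[i];
    double yi = bb[0] * xi + z[0];
    for (int k = 0; k < nf - 2; ++k)
      z[k] = bb[k + 1] * xi + z[k + 1] - aa[k + 1] * yi;
    z[nf - 2] = bb[nf - 1] * xi - aa[nf - 1] * yi;
    y[i] = yi;
  }
  return y;
}
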