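#include <Rcpp.h>
using namespace Rcpp;

// Direct-form II transposed IIR filter, y = filter(b, a, x).
// a[0] must be non-zero; coefficients are normalised by a[0] internally.
// [[Rcpp::export]]
NumericVector iir_filter_cpp(NumericVector b, NumericVector a, NumericVector x) {
  int nb = b.size(), na = a.size(), n = x.size();
  int nk = std::max(nb, na);
  std::vector<double> bb(nk, 0.0), aa(nk, 0.0), z(nk, 0.0);
  double a0 = a[0];
  for (int i = 0; i < nb; ++i) bb[i] = b[i] / a0;
  for (int i = 0; i < na; ++i) aa[i] = a[i] / a0;
  NumericVector yv(n);
  const double* xs = REAL(x);
  double* ys = REAL(yv);
  for (int i = 0; i < n; ++i) {
    double xi = xs[i];
    double yi = bb[0] * xi + z[0];
    for (int k = 1; k < nk; ++k)
      z[k - 1] = bb[k] * xi - aa[k] * yi + z[k];
    ys[i] = yi;
  }
  return yv;
}
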