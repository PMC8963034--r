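#include <Rcpp.h>
using namespace Rcpp;

// Direct-form II transposed IIR filter. b, a are full-length coefficient
// vectors (a[0] may differ from 1; both are normalized here). zi is the
// initial delay-line state of length max(length(a), length(b)) - 1, or
// empty for a zero initial state.
// [[Rcpp::export]]
NumericVector iir_filter_cpp(NumericVector b, NumericVector a,
                             NumericVector x, NumericVector zi) {
  const int n  = x.size();
  const int nf = std::max(a.size(), b.size());
  std::vector<double> bb(nf, 0.0), aa(nf, 0.0), z(nf - 1, 0.0);
  for (int i = 0; i < b.size(); ++i) bb[i] = b[i];
  for (int i = 0; i < a.size(); ++i) aa[i] = a[i];
  const double a0 = aa[0];
  if (a0 == 0.0) stop("a[1] must be nonzero");
  for (int i = 0; i < nf; ++i) { bb[i] /= a0; aa[i] /= a0; }
  if (zi.size() == nf - 1)
    for (int i = 0; i < nf - 1; ++i) z[i] = zi[i];
  else if (zi.size() != 0)
    stop("zi must have length max(length(a), length(b)) - 1");

  NumericVector y(n);
  for (int i = 0; i < n; ++i) {
    const double xi = x[i];
    const double yi = bb[0] * xi + z[0];
    for (int j = 0; j < nf - 2; ++j)
      z[j] = bb[j + 1] * xi + z[j + 1] - aa[j + 1] * yi;
    z[nf - 2] = bb[nf - 1] * xi - aa[nf - 1] * yi;
    y[i] = yi;
  }
  return y;
}
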