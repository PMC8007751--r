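#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// One causal IIR pass (direct form II transposed, zero initial state)
// applied independently to each column of x. Coefficients are the
// usual b (numerator) and a (denominator, a[0] = 1) vectors.
// [[Rcpp::export(name = ".iirPassCpp")]]
NumericMatrix iir_pass(NumericVector b, NumericVector a, NumericMatrix x) {
  const int n = x.nrow(), m = x.ncol();
  const int nb = b.size(), na = a.size();
  const int nz = std::max(nb, na) - 1;
  if (na < 1 || a[0] == 0.0) stop("a[0] must be non-zero");
  std::vector<double> bb(nz + 1, 0.0), aa(nz + 1, 0.0);
  for (int i = 0; i < nb; ++i) bb[i] = b[i] / a[0];
  for (int i = 0; i < na; ++i) aa[i] = a[i] / a[0];
  NumericMatrix y(n, m);
  std::vector<double> z(std::max(nz, 1), 0.0);
  const double* xp = x.begin();
  double* yp = y.begin();
  for (int j = 0; j < m; ++j) {
    std::fill(z.begin(), z.end(), 0.0);
    const double* xc = xp + static_cast<size_t>(j) * n;
    double* yc = yp + static_cast<size_t>(j) * n;
    for (int i = 0; i < n; ++i) {
      const double xi = xc[i];
      const double yi = bb[0] * xi + (nz > 0 ? z[0] : 0.0);
      for (int k = 0; k < nz - 1; ++k) {
        z[k] = bb[k + 1] * xi + z[k + 1] - aa[k + 1] * yi;
      }
      if (nz > 0) z[nz - 1] = bb[nz] * xi - aa[nz] * yi;
      yc[i] = yi;
    }
  }
  return y;
}
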