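#include <Rcpp.h>
using namespace Rcpp;

// Heteroscedasticity-scaled Euclidean distance between all pairs of
// individuals, each coordinate standardised by the sum of the two
// individuals' variances (already on the noise scale). Inputs are
// coefficient-major (p x n): one contiguous column per individual, so the
// inner loop is cache-friendly. Coordinates where the summed variance is
// exactly zero contribute zero when the difference is also zero (the
// baselined first coefficient); the R wrapper rejects any other
// zero-variance coordinate before calling this kernel.
// [[Rcpp::export]]
NumericMatrix dist_scaled_cpp(NumericMatrix Mt, NumericMatrix Vdt) {
  const int p = Mt.nrow(), n = Mt.ncol();
  NumericMatrix D(n, n);
  const double *m = REAL(Mt), *v = REAL(Vdt);
  for (int i = 0; i < n; ++i) {
    const double *mi = m + (size_t)i * p, *vi = v + (size_t)i * p;
    for (int j = i + 1; j < n; ++j) {
      const double *mj = m + (size_t)j * p, *vj = v + (size_t)j * p;
      double acc = 0.0;
      for (int k = 0; k < p; ++k) {
        const double s = vi[k] + vj[k];
        if (s > 0.0) {
          const double d = mi[k] - mj[k];
          acc += d * d / s;
        }
      }
      const double dist = std::sqrt(acc);
      D(i, j) = dist;
      D(j, i) = dist;
    }
  }
  return D;
}
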