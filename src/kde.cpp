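#include <Rcpp.h>
using namespace Rcpp;

// Gaussian product-kernel density estimates evaluated at arbitrary points.
// Direct O(n_eval * n_sample) sums; sample sizes here are <= a few thousand.

static const double INV_SQRT_2PI = 0.3989422804014327;

// [[Rcpp::export(name = ".kde_logf_1d")]]
NumericVector kde_logf_1d(NumericVector at, NumericVector samples, double h) {
  const int m = at.size(), n = samples.size();
  NumericVector out(m);
  const double inv_h = 1.0 / h;
  for (int i = 0; i < m; ++i) {
    double acc = 0.0;
    const double ai = at[i];
    for (int j = 0; j < n; ++j) {
      const double z = (ai - samples[j]) * inv_h;
      acc += std::exp(-0.5 * z * z);
    }
    out[i] = std::log(acc * INV_SQRT_2PI * inv_h / n);
  }
  return out;
}

// [[Rcpp::export(name = ".kde_logf_2d")]]
NumericVector kde_logf_2d(NumericVector at1, NumericVector at2,
                          NumericVector s1, NumericVector s2,
                          double h1, double h2) {
  const int m = at1.size(), n = s1.size();
  NumericVector out(m);
  const double inv_h1 = 1.0 / h1, inv_h2 = 1.0 / h2;
  const double norm = INV_SQRT_2PI * INV_SQRT_2PI * inv_h1 * inv_h2;
  for (int i = 0; i < m; ++i) {
    double acc = 0.0;
    const double a1 = at1[i], a2 = at2[i];
    for (int j = 0; j < n; ++j) {
      const double z1 = (a1 - s1[j]) * inv_h1;
      const double z2 = (a2 - s2[j]) * inv_h2;
      acc += std::exp(-0.5 * (z1 * z1 + z2 * z2));
    }
    out[i] = std::log(acc * norm / n);
  }
  return out;
}
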