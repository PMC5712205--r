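#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// signed model-based concordance probability: mean over unordered pairs of
// 1 / (1 + exp(-z |x_i - x_j|)) with z = (direction sign) * beta; tied
// covariates contribute exactly 1/2 (|dx| = 0)
// [[Rcpp::export(name = ".cp_pairwise_cpp")]]
double cp_pairwise_cpp(double z, NumericVector x) {
  R_xlen_t n = x.size();
  double tot = 0.0;
  for (R_xlen_t i = 0; i < n - 1; ++i) {
    double xi = x[i];
    for (R_xlen_t j = i + 1; j < n; ++j) {
      double d = std::fabs(xi - x[j]);
      tot += 1.0 / (1.0 + std::exp(-z * d));
    }
  }
  return tot / (0.5 * static_cast<double>(n) * static_cast<double>(n - 1));
}
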