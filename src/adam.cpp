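#include <Rcpp.h>
using namespace Rcpp;

// In-place Adam update over a list of parameter arrays. The caller owns
// unshared copies of params/m/v (train loops duplicate them once at entry);
// updating in place avoids reallocating several hundred megabytes per
// optimisation step, which dominates the runtime of the training loops in
// pure R.
// [[Rcpp::export(rng = false)]]
void adam_update_inplace(List params, List grads, List m, List v,
                         double lr, double beta1, double beta2,
                         double eps, int t) {
  const double bc1 = 1.0 - std::pow(beta1, t);
  const double bc2 = 1.0 - std::pow(beta2, t);
  for (R_xlen_t k = 0; k < params.size(); ++k) {
    NumericVector p = params[k];
    NumericVector g = grads[k];
    NumericVector mm = m[k];
    NumericVector vv = v[k];
    const R_xlen_t n = p.size();
    if (g.size() != n || mm.size() != n || vv.size() != n)
      stop("adam_update_inplace: shape mismatch at parameter %d", (int)k + 1);
    for (R_xlen_t i = 0; i < n; ++i) {
      mm[i] = beta1 * mm[i] + (1.0 - beta1) * g[i];
      vv[i] = beta2 * vv[i] + (1.0 - beta2) * g[i] * g[i];
      p[i] -= lr * (mm[i] / bc1) / (std::sqrt(vv[i] / bc2) + eps);
    }
  }
}
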