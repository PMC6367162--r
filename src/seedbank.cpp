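#include <Rcpp.h>
using namespace Rcpp;

// Iterate the density-dependent seed-bank recursion
//   n_{t+1} = g K_t s_new n_t / (1 + a g n_t) + (1 - g) s_old n_t
// for a given yield sequence K. Returns n_0..n_T (length T + 1).
// [[Rcpp::export]]
NumericVector seedbank_path_cpp(double n0, double g, NumericVector K,
                                double s_new, double s_old, double a) {
  const R_xlen_t T = K.size();
  NumericVector n(T + 1);
  n[0] = n0;
  for (R_xlen_t t = 0; t < T; ++t) {
    const double nt = n[t];
    n[t + 1] = g * K[t] * s_new * nt / (1.0 + a * g * nt)
             + (1.0 - g) * s_old * nt;
  }
  return n;
}
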