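#include <Rcpp.h>
using namespace Rcpp;

// Single-site Gibbs sampler for the {0,1}-coded Ising model
//   P(x) ∝ exp(sum_i tau_i x_i + sum_{i<j} J_ij x_i x_j)
// Conditional: logit P(x_i = 1 | rest) = tau_i + sum_j J_ij x_j.
// One sweep updates all p sites in order; one row is retained every `thin`
// sweeps after `burn_in` sweeps. Uses R's RNG so set.seed() controls output.
// [[Rcpp::export]]
IntegerMatrix gibbs_sample_cpp(NumericMatrix J, NumericVector tau, int n,
                               int burn_in, int thin) {
  int p = J.nrow();
  IntegerMatrix out(n, p);
  std::vector<int> x(p);
  for (int i = 0; i < p; ++i) x[i] = (unif_rand() < 0.5) ? 1 : 0;

  int total_sweeps = burn_in + n * thin;
  int kept = 0;
  for (int s = 0; s < total_sweeps; ++s) {
    for (int i = 0; i < p; ++i) {
      double eta = tau[i];
      for (int j = 0; j < p; ++j) {
        if (x[j]) eta += J(j, i);
      }
      double pr = 1.0 / (1.0 + std::exp(-eta));
      x[i] = (unif_rand() < pr) ? 1 : 0;
    }
    if (s >= burn_in && (s - burn_in + 1) % thin == 0) {
      for (int i = 0; i < p; ++i) out(kept, i) = x[i];
      ++kept;
      if (kept == n) break;
    }
  }
  return out;
}
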