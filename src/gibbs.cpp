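#include <Rcpp.h>
using namespace Rcpp;

// Coordinate-wise Gibbs sampler for the uniform distribution on the utility
// polytope: the unit cube intersected with strict-order constraints
// u[worse] < u[better] and a block gap min(non-lethal) >= max(lethal) + delta.
// Each coordinate is resampled uniformly on the interval its neighbours and
// the gap allow; the conditional of a uniform joint is uniform, so sweeps
// leave the target invariant. Uses R's RNG so set.seed() governs the chain.
//
// init must satisfy every constraint. worse/better are 0-based coordinate
// indices per edge; lethal flags the coordinates on the lethal side of the
// gap (ignored when no coordinate is lethal or none is non-lethal).
// [[Rcpp::export]]
NumericMatrix gibbs_polytope_cpp(NumericVector init,
                                 IntegerVector worse,
                                 IntegerVector better,
                                 LogicalVector lethal,
                                 double delta,
                                 int n_keep, int burn_in, int thin) {
  const int k = init.size();
  const int n_edges = worse.size();
  std::vector<double> u(init.begin(), init.end());
  NumericMatrix out(n_keep, k);

  bool any_lethal = false, any_nonlethal = false;
  for (int c = 0; c < k; ++c) (lethal[c] ? any_lethal : any_nonlethal) = true;
  const bool use_gap = any_lethal && any_nonlethal;

  const long total_sweeps = (long)burn_in + (long)n_keep * thin;
  int kept = 0;
  RNGScope scope;
  for (long s = 0; s < total_sweeps; ++s) {
    for (int c = 0; c < k; ++c) {
      double lo = 0.0, hi = 1.0;
      for (int e = 0; e < n_edges; ++e) {
        if (better[e] == c && u[worse[e]] > lo) lo = u[worse[e]];
        if (worse[e] == c && u[better[e]] < hi) hi = u[better[e]];
      }
      if (use_gap) {
        if (lethal[c]) {
          double min_nl = 1.0;
          for (int j = 0; j < k; ++j)
            if (!lethal[j] && u[j] < min_nl) min_nl = u[j];
          if (min_nl - delta < hi) hi = min_nl - delta;
        } else {
          double max_l = 0.0;
          for (int j = 0; j < k; ++j)
            if (lethal[j] && u[j] > max_l) max_l = u[j];
          if (max_l + delta > lo) lo = max_l + delta;
        }
      }
      // feasible current point guarantees lo <= u[c] <= hi
      u[c] = R::runif(lo, hi);
    }
    if (s >= burn_in && (s - burn_in) % thin == thin - 1) {
      for (int c = 0; c < k; ++c) out(kept, c) = u[c];
      ++kept;
      if (kept == n_keep) break;
    }
  }
  return out;
}
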