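#include <Rcpp.h>
using namespace Rcpp;

// Euler-Maruyama simulation of a Wiener diffusion between absorbing
// boundaries 0 (no/refuse) and a (yes/eat), starting at z_rel * a, with
// per-trial drift v and unit diffusion coefficient. Passage times beyond
// max_decision_t are censored (choice coded 0 = missed). Uses R's RNG so
// set.seed() governs reproducibility.
//
// Returns a two-column matrix: column 1 choice (1 = upper/yes,
// -1 = lower/no, 0 = missed), column 2 decision time in seconds (NA when
// missed).
// [[Rcpp::export(name = ".ddm_simulate_cpp")]]
NumericMatrix ddm_simulate_cpp(NumericVector v, double a, double z_rel,
                               double dt, double max_decision_t) {
  const int n = v.size();
  NumericMatrix out(n, 2);
  const double sqdt = std::sqrt(dt);
  const int max_steps = (int)std::ceil(max_decision_t / dt);
  for (int i = 0; i < n; ++i) {
    double x = z_rel * a;
    const double drift_step = v[i] * dt;
    int step = 0;
    int choice = 0;
    while (step < max_steps) {
      x += drift_step + sqdt * norm_rand();
      ++step;
      if (x >= a) { choice = 1; break; }
      if (x <= 0.0) { choice = -1; break; }
    }
    out(i, 0) = choice;
    out(i, 1) = (choice == 0) ? NA_REAL : step * dt;
  }
  return out;
}
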