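#include <Rcpp.h>
using namespace Rcpp;

// Gillespie direct-method simulation of one lesion-kinetics path.
// Channels (all consume sublethal lesions, so at most x0 events occur):
//   repair:   x -> x - 1           at rate r * x
//   direct:   x -> x - 1, y -> y+1 at rate x * (a + a_logistic * x)
//   pairwise: x -> x - 2, y -> y+1 at rate b_tilde * x * (x - 1)
// Uses R's RNG so set.seed() governs reproducibility.
// [[Rcpp::export(name = ".simulate_path_cpp")]]
NumericMatrix simulate_path_cpp(int x0, int y0, double t_max,
                                double r, double a, double b_tilde,
                                double a_logistic) {
  int cap = x0 + 1;
  NumericMatrix out(cap, 3); // t, x, y
  int x = x0, y = y0, n = 0;
  double t = 0.0;
  out(0, 0) = 0.0; out(0, 1) = x; out(0, 2) = y; n = 1;
  while (x > 0) {
    double a1 = r * x;
    double a2 = x * (a + a_logistic * x);
    double a3 = b_tilde * x * (x - 1.0);
    double a0 = a1 + a2 + a3;
    if (a0 <= 0.0) break;
    t += R::exp_rand() / a0;
    if (t > t_max) break;
    double u = unif_rand() * a0;
    if (u < a1) {
      x -= 1;                      // repair
    } else if (u < a1 + a2) {
      x -= 1; y += 1;              // direct lethal conversion
    } else {
      x -= 2; y += 1;              // pairwise interaction
    }
    out(n, 0) = t; out(n, 1) = x; out(n, 2) = y; n++;
  }
  return out(Range(0, n - 1), _);
}

// States of one event-driven path sampled onto an observation grid
// (right-continuous step function).
// [[Rcpp::export(name = ".sample_on_grid_cpp")]]
IntegerMatrix sample_on_grid_cpp(NumericMatrix path, NumericVector t_points) {
  int m = t_points.size();
  IntegerMatrix out(m, 2);
  int k = 0, last = path.nrow() - 1;
  for (int i = 0; i < m; ++i) {
    while (k < last && path(k + 1, 0) <= t_points[i]) ++k;
    out(i, 0) = (int) path(k, 1);
    out(i, 1) = (int) path(k, 2);
  }
  return out;
}
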