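#include <Rcpp.h>
using namespace Rcpp;

// transition intensities of the time-continuous Moran chain with
// directional selection and recurrent mutation
static inline void moran_rates(int i, int N, double s, double mu,
                               double &q_up, double &q_down) {
  q_up = (double)(N - i) * i / N + mu * (N - i);
  q_down = (double)i * (1.0 - s) * (N - i) / N;
}

// Gillespie simulation storing every jump (sparse representation).
// Uses R's RNG (exp_rand/unif_rand) so set.seed() controls reproducibility.
// [[Rcpp::export]]
List cpp_simulate_trajectory(int N, double s, double mu, int i0,
                             double t_max, double max_events) {
  std::vector<double> times;
  std::vector<int> states;
  double t = 0.0, q_up, q_down;
  int i = i0;
  double n_events = 0.0;
  bool hit_horizon = false;

  for (;;) {
    moran_rates(i, N, s, mu, q_up, q_down);
    double Q = q_up + q_down;
    if (Q <= 0.0) break;  // absorbed (state N, or 0 when mu == 0)
    double tau = exp_rand() / Q;
    if (t + tau > t_max) { hit_horizon = true; break; }
    t += tau;
    i += (unif_rand() * Q < q_up) ? 1 : -1;
    times.push_back(t);
    states.push_back(i);
    if (++n_events > max_events)
      stop("event-count cap exceeded (%g events); check parameters "
           "or raise max_events", max_events);
  }

  return List::create(_["times"] = wrap(times), _["states"] = wrap(states),
                      _["final_state"] = i, _["t_end"] = hit_horizon ? t_max : t,
                      _["absorbed"] = !hit_horizon);
}

// Simulate and record only the state at each (sorted, increasing) grid time:
// right-continuous sampling, no jump storage. Used for ensembles at large N.
// [[Rcpp::export]]
IntegerVector cpp_simulate_on_grid(int N, double s, double mu, int i0,
                                   NumericVector t_grid, double max_events) {
  int G = t_grid.size();
  IntegerVector out(G);
  double t = 0.0, q_up, q_down;
  int i = i0, idx = 0;
  double n_events = 0.0;

  while (idx < G) {
    moran_rates(i, N, s, mu, q_up, q_down);
    double Q = q_up + q_down;
    if (Q <= 0.0) {                     // absorbed: state holds forever
      for (; idx < G; ++idx) out[idx] = i;
      break;
    }
    double t_next = t + exp_rand() / Q;
    while (idx < G && t_grid[idx] < t_next) out[idx++] = i;
    if (idx == G) break;
    t = t_next;
    i += (unif_rand() * Q < q_up) ? 1 : -1;
    if (++n_events > max_events)
      stop("event-count cap exceeded (%g events); check parameters "
           "or raise max_events", max_events);
  }
  return out;
}
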