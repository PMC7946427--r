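#include <Rcpp.h>
using namespace Rcpp;

// Hybrid simulation of the receptor + push-pull network driven by an
// Ornstein-Uhlenbeck ligand signal.  The OU input uses its exact
// discretization.  Molecule counts evolve as independent two-state chains
// with rates held piecewise constant over dt; per-molecule transition
// probabilities use the exact two-state propagator for those frozen rates,
// so the update is unbiased for a static input, and realized transitions
// are attributed to the competing channels by binomial thinning.  The only
// residual discretization error is the rate-freezing itself, controlled by
// requiring every per-step event probability <= 0.1.  Uses R's RNG, so
// runs are reproducible from set.seed().

static inline int binom_draw(int n, double p) {
  if (n <= 0 || p <= 0.0) return 0;
  return (int) R::rbinom((double) n, p);
}

// [[Rcpp::export(name = ".sim_network_cpp")]]
List sim_network_cpp(double L_mean, double sigma_L, double tau_L,
                     int R_T, double k1, double k2,
                     int X_T, double kf, double kmf, double kr, double kmr,
                     double dt, double n_steps_d, double n_burn_d,
                     int record_every) {
  const long n_steps = (long) n_steps_d;
  const long n_burn = (long) n_burn_d;
  const double a_ou = std::exp(-dt / tau_L);
  const double s_ou = sigma_L * std::sqrt(1.0 - a_ou * a_ou);

  // stationary initial condition at the mean signal
  const double p0 = k1 * L_mean / (k1 * L_mean + k2);
  double L = L_mean + sigma_L * R::norm_rand();
  if (L < 0.0) L = 0.0;
  int RL = binom_draw(R_T, p0);
  const double act0 = kf * p0 * R_T + kmr, dea0 = kmf * p0 * R_T + kr;
  int Xs = binom_draw(X_T, act0 / (act0 + dea0));

  const long n_rec = n_steps / record_every;
  NumericVector rec_t(n_rec), rec_L(n_rec);
  IntegerVector rec_RL(n_rec), rec_X(n_rec);

  long clamped = 0, rec_i = 0;
  double max_prob = 0.0;
  double net_flux = 0.0;           // receptor-catalysed net activations
  const long total = n_burn + n_steps;

  for (long step = 0; step < total; ++step) {
    // ligand (exact OU update, clamped at 0)
    L = L_mean + (L - L_mean) * a_ou + s_ou * R::norm_rand();
    if (L < 0.0) { L = 0.0; if (step >= n_burn) ++clamped; }

    // receptor binding / unbinding: exact two-state propagator at frozen L
    {
      const double a = k1 * L, b = k2, S = a + b;
      const double relax = -std::expm1(-S * dt);
      const double p_on = (a / S) * relax;        // free  -> bound
      const double p_off = (b / S) * relax;       // bound -> free
      if (p_on > max_prob) max_prob = p_on;
      if (p_off > max_prob) max_prob = p_off;
      RL += binom_draw(R_T - RL, p_on) - binom_draw(RL, p_off);
    }

    // readout cycle at the current RL: exact two-state propagator for the
    // combined activation/deactivation rates, then binomial thinning to
    // attribute transitions to the receptor-catalysed channel
    {
      const double alpha = kf * RL + kmr;         // x  -> x*
      const double delta = kmf * RL + kr;         // x* -> x
      const double S = alpha + delta;
      const double relax = -std::expm1(-S * dt);
      const double p_up = (alpha / S) * relax;
      const double p_down = (delta / S) * relax;
      if (p_up > max_prob) max_prob = p_up;
      if (p_down > max_prob) max_prob = p_down;
      const int n_up = binom_draw(X_T - Xs, p_up);
      const int n_down = binom_draw(Xs, p_down);
      Xs += n_up - n_down;
      if (step >= n_burn) {
        const int up_rec = binom_draw(n_up, alpha > 0.0 ? kf * RL / alpha : 0.0);
        const int down_rec = binom_draw(n_down, delta > 0.0 ? kmf * RL / delta : 0.0);
        net_flux += (double) (up_rec - down_rec);
      }
    }

    if (step >= n_burn) {
      const long k = step - n_burn;
      if ((k + 1) % record_every == 0 && rec_i < n_rec) {
        rec_t[rec_i] = (k + 1) * dt;
        rec_L[rec_i] = L;
        rec_RL[rec_i] = RL;
        rec_X[rec_i] = Xs;
        ++rec_i;
      }
    }
  }

  return List::create(
    _["times"] = rec_t, _["L"] = rec_L, _["RL"] = rec_RL,
    _["X_star"] = rec_X,
    _["clamped_fraction"] = (double) clamped / (double) n_steps,
    _["max_event_prob"] = max_prob,
    _["net_flux_rate"] = net_flux / (n_steps * dt));
}

// [[Rcpp::export(name = ".sim_ou_cpp")]]
List sim_ou_cpp(double L_mean, double sigma_L, double tau_L,
                double dt, double n_steps_d, double n_burn_d,
                int record_every) {
  const long n_steps = (long) n_steps_d;
  const long n_burn = (long) n_burn_d;
  const double a_ou = std::exp(-dt / tau_L);
  const double s_ou = sigma_L * std::sqrt(1.0 - a_ou * a_ou);
  double L = L_mean + sigma_L * R::norm_rand();
  if (L < 0.0) L = 0.0;
  const long n_rec = n_steps / record_every;
  NumericVector rec_t(n_rec), rec_L(n_rec);
  long clamped = 0, rec_i = 0;
  const long total = n_burn + n_steps;
  for (long step = 0; step < total; ++step) {
    L = L_mean + (L - L_mean) * a_ou + s_ou * R::norm_rand();
    if (L < 0.0) { L = 0.0; if (step >= n_burn) ++clamped; }
    if (step >= n_burn) {
      const long k = step - n_burn;
      if ((k + 1) % record_every == 0 && rec_i < n_rec) {
        rec_t[rec_i] = (k + 1) * dt;
        rec_L[rec_i] = L;
        ++rec_i;
      }
    }
  }
  return List::create(
    _["times"] = rec_t, _["L"] = rec_L,
    _["clamped_fraction"] = (double) clamped / (double) n_steps);
}
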