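#include <Rcpp.h>
using namespace Rcpp;

// Poisson tau-leap integrator for the temperature-forced tritrophic model.
//
// States (integer counts held as doubles): C, P, W, E, N.
// day_rates: one row per simulated day with columns
//   0 rT      crop growth rate r * TF(T)
//   1 mu      adult death rate mu(T) (run-level noise factor applied)
//   2 w1      psi1 * omega1(T) egg maturation rate (factor applied)
//   3 w2      psi2 * omega2(T) nymph maturation rate (factor applied)
//   4 a1      feeding rate (repellent-modulated when scheduled)
//   5 lam     enemy attraction rate (attractant-modulated when scheduled)
// variant: 0 = egg parasitoid, 1 = predator on nymphs/adults.
// All propensities are evaluated at the start of each leap; any species
// driven negative is clamped to zero and the clamp counted.
// [[Rcpp::export(name = ".tau_leap_run_cpp")]]
List tau_leap_run_cpp(NumericVector init, NumericMatrix day_rates,
                      List pars, double tau, int steps_per_day, int variant) {
  const double K  = pars["K"],  b1 = pars["b1"], b2 = pars["b2"];
  const double a2 = pars["a2"], c1 = pars["c1"], c2 = pars["c2"];
  const double h  = pars["h"],  delta = pars["delta"];
  const int n_days = day_rates.nrow();

  double C = init[0], P = init[1], W = init[2], E = init[3], N = init[4];
  NumericMatrix out(n_days + 1, 5);
  out(0, 0) = C; out(0, 1) = P; out(0, 2) = W; out(0, 3) = E; out(0, 4) = N;
  long clamps = 0;

  for (int d = 0; d < n_days; ++d) {
    const double rT = day_rates(d, 0), mu = day_rates(d, 1);
    const double w1 = day_rates(d, 2), w2 = day_rates(d, 3);
    const double a1 = day_rates(d, 4), lam = day_rates(d, 5);
    for (int s = 0; s < steps_per_day; ++s) {
      const double PN   = P + N;
      const double feed = a1 * C * PN / (b1 + C);
      const double ovip = c1 * a1 * C * P / (b1 + C);

      const double birth = R::rpois(rT * C * tau);
      const double dd    = R::rpois(rT * C * C / K * tau);
      const double eat   = R::rpois(feed * tau);
      const double harv  = R::rpois(h * C * tau);
      const double lay   = R::rpois(ovip * tau);
      const double em    = R::rpois(w1 * E * tau);
      const double nm    = R::rpois(w2 * N * tau);
      const double ad    = R::rpois(mu * P * tau);
      const double attr  = R::rpois(lam * feed * tau);
      const double disp  = R::rpois(delta * W * tau);

      double par = 0, rec = 0, predP = 0, predN = 0;
      if (variant == 0) {
        const double ph = a2 * E * W / (b2 + E);
        par = R::rpois(ph * tau);
        rec = R::rpois(c2 * ph * tau);
      } else {
        const double denom = b2 + PN;
        predP = R::rpois(a2 * P * W / denom * tau);
        predN = R::rpois(a2 * N * W / denom * tau);
        rec   = R::rpois(c2 * a2 * PN * W / denom * tau);
      }

      C += birth - dd - eat - harv;
      P += nm - ad - predP;
      W += rec + attr - disp;
      E += lay - em - par;
      N += em - nm - predN;

      if (C < 0) { C = 0; ++clamps; }
      if (P < 0) { P = 0; ++clamps; }
      if (W < 0) { W = 0; ++clamps; }
      if (E < 0) { E = 0; ++clamps; }
      if (N < 0) { N = 0; ++clamps; }
    }
    out(d + 1, 0) = C; out(d + 1, 1) = P; out(d + 1, 2) = W;
    out(d + 1, 3) = E; out(d + 1, 4) = N;
  }
  return List::create(_["states"] = out, _["clamps"] = (double) clamps,
                      _["steps"] = (double) n_days * steps_per_day * 1.0);
}
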