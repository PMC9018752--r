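#include <Rcpp.h>
using namespace Rcpp;

// Deterministic kinetics of one reporter well under drug treatment.
//
// State y = (N_live, N_apop, N_nec, m, c, g, P):
//   dN_live/dt = r (1 - arrest u(t)) N_live (1 - N_tot/K) - k_d 1[t>t_death] N_live
//   dN_apop/dt = k_d 1[t>t_death] N_live - k_n N_apop
//   dN_nec/dt  = k_n N_apop
//   dm/dt      = alpha0 (1 + (beta-1) u(t)) - delta_m m
//   dc/dt      = k_c m - delta_c c
//   dg/dt      = k_g m - delta_g g
//   dP/dt      = k_p c (N_live + eps_apop N_apop)
// with induction/arrest ramp u(t) = 1 - exp(-t/tau_ind).
//
// Fixed-step classical RK4; the caller picks the internal step (<= 0.5 h).

struct Pars {
  double r, K, alpha0, delta_m, k_c, delta_c, k_g, delta_g, k_p, eps_apop;
  double arrest, beta, tau_ind, t_death, k_d, k_n;
};

static inline void deriv(double t, const double* y, double* dy, const Pars& p,
                         bool death_on) {
  const double u = (p.tau_ind > 0.0) ? 1.0 - std::exp(-t / p.tau_ind) : 1.0;
  const double Nl = y[0], Na = y[1], Nn = y[2], m = y[3], c = y[4], g = y[5];
  const double Ntot = Nl + Na + Nn;
  const double grow = p.r * (1.0 - p.arrest * u) * Nl * (1.0 - Ntot / p.K);
  const double die = death_on ? p.k_d * Nl : 0.0;
  dy[0] = grow - die;
  dy[1] = die - p.k_n * Na;
  dy[2] = p.k_n * Na;
  dy[3] = p.alpha0 * (1.0 + (p.beta - 1.0) * u) - p.delta_m * m;
  dy[4] = p.k_c * m - p.delta_c * c;
  dy[5] = p.k_g * m - p.delta_g * g;
  dy[6] = p.k_p * c * (Nl + p.eps_apop * Na);
}

// [[Rcpp::export(name = ".sim_kinetics_cpp")]]
NumericMatrix sim_kinetics_cpp(NumericVector pars, NumericVector times,
                               double h_max, NumericVector init) {
  Pars p;
  p.r = pars["r"]; p.K = pars["K"];
  p.alpha0 = pars["alpha0"]; p.delta_m = pars["delta_m"];
  p.k_c = pars["k_c"]; p.delta_c = pars["delta_c"];
  p.k_g = pars["k_g"]; p.delta_g = pars["delta_g"];
  p.k_p = pars["k_p"]; p.eps_apop = pars["eps_apop"];
  p.arrest = pars["arrest"]; p.beta = pars["beta"];
  p.tau_ind = pars["tau_ind"]; p.t_death = pars["t_death"];
  p.k_d = pars["k_d"]; p.k_n = pars["k_n"];

  const int nt = times.size();
  NumericMatrix out(nt, 8);
  double y[7], k1[7], k2[7], k3[7], k4[7], tmp[7];
  for (int j = 0; j < 7; ++j) y[j] = init[j];

  out(0, 0) = times[0];
  for (int j = 0; j < 7; ++j) out(0, j + 1) = y[j];

  for (int i = 1; i < nt; ++i) {
    const double t0 = times[i - 1], t1 = times[i];
    const int nsub = (int)std::ceil((t1 - t0) / h_max - 1e-9);
    const double h = (t1 - t0) / nsub;
    double t = t0;
    for (int s = 0; s < nsub; ++s) {
      // the death indicator 1[t > t_death] switches per whole step; the
      // caller inserts t_death into the sampling grid, so no step straddles
      // the discontinuity and the RHS is smooth within every step
      const bool death_on = (t >= p.t_death - 1e-9);
      deriv(t, y, k1, p, death_on);
      for (int j = 0; j < 7; ++j) tmp[j] = y[j] + 0.5 * h * k1[j];
      deriv(t + 0.5 * h, tmp, k2, p, death_on);
      for (int j = 0; j < 7; ++j) tmp[j] = y[j] + 0.5 * h * k2[j];
      deriv(t + 0.5 * h, tmp, k3, p, death_on);
      for (int j = 0; j < 7; ++j) tmp[j] = y[j] + h * k3[j];
      deriv(t + h, tmp, k4, p, death_on);
      for (int j = 0; j < 7; ++j) {
        y[j] += h / 6.0 * (k1[j] + 2.0 * k2[j] + 2.0 * k3[j] + k4[j]);
        if (y[j] < 0.0) y[j] = 0.0;  // clip numerical undershoot
      }
      t += h;
      if (!R_finite(y[0]) || !R_finite(y[6]))
        stop("kinetics integration diverged at t = %f h", t);
    }
    out(i, 0) = t1;
    for (int j = 0; j < 7; ++j) out(i, j + 1) = y[j];
  }
  colnames(out) = CharacterVector::create(
    "time_h", "n_live", "n_apop", "n_nec", "mrna", "cox2", "gfp", "pge2_pg_ml");
  return out;
}
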