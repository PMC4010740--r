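// Hodgkin-Huxley population integrator.
//
// Each neuron integrates the classic squid-axon HH equations with
// alpha-function synaptic conductances, g(t) = gmax * x * exp(1 - x),
// x = (t - t0)/tau_syn, I_syn = g(t) * (E_syn - V).  Neurons within a
// population are uncoupled (all coupling is between populations and is
// delivered as the event list), so each neuron is integrated
// independently with a fixed-step RK4 scheme.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

struct HHParams {
  double C, gNa, gK, gL, ENa, EK, EL, Esyn, tau_syn;
};

static inline double alpha_m(double V) {
  double x = V + 40.0;
  if (std::fabs(x) < 1e-7) return 1.0;  // limit of 0.1*x/(1-exp(-x/10))
  return 0.1 * x / (1.0 - std::exp(-x / 10.0));
}
static inline double beta_m(double V) { return 4.0 * std::exp(-(V + 65.0) / 18.0); }
static inline double alpha_h(double V) { return 0.07 * std::exp(-(V + 65.0) / 20.0); }
static inline double beta_h(double V) { return 1.0 / (1.0 + std::exp(-(V + 35.0) / 10.0)); }
static inline double alpha_n(double V) {
  double x = V + 55.0;
  if (std::fabs(x) < 1e-7) return 0.1;
  return 0.01 * x / (1.0 - std::exp(-x / 10.0));
}
static inline double beta_n(double V) { return 0.125 * std::exp(-(V + 65.0) / 80.0); }

// total synaptic conductance at time t from this neuron's events
static inline double syn_g(double t, const std::vector<double>& et,
                           const std::vector<double>& eg, double tau) {
  double g = 0.0;
  for (size_t i = 0; i < et.size(); ++i) {
    double x = (t - et[i]) / tau;
    if (x > 0.0 && x < 20.0) g += eg[i] * x * std::exp(1.0 - x);
  }
  return g;
}

struct Deriv {
  double dV, dm, dh, dn;
};

static inline Deriv hh_deriv(double V, double m, double h, double n,
                             double gsyn, const HHParams& p) {
  Deriv d;
  double INa = p.gNa * m * m * m * h * (V - p.ENa);
  double IK = p.gK * n * n * n * n * (V - p.EK);
  double IL = p.gL * (V - p.EL);
  double Isyn = gsyn * (p.Esyn - V);
  d.dV = (-INa - IK - IL + Isyn) / p.C;
  d.dm = alpha_m(V) * (1.0 - m) - beta_m(V) * m;
  d.dh = alpha_h(V) * (1.0 - h) - beta_h(V) * h;
  d.dn = alpha_n(V) * (1.0 - n) - beta_n(V) * n;
  return d;
}

// [[Rcpp::export(name = ".hh_pop_sim")]]
List hh_pop_sim(NumericVector event_time, NumericVector event_g,
                IntegerVector event_neuron, int n_neurons, double t_end,
                double dt, NumericVector params) {
  HHParams p;
  p.C = params["C"]; p.gNa = params["gNa"]; p.gK = params["gK"];
  p.gL = params["gL"]; p.ENa = params["ENa"]; p.EK = params["EK"];
  p.EL = params["EL"]; p.Esyn = params["Esyn"]; p.tau_syn = params["tau_syn"];

  // resting state for V0 = -65 mV
  double V0 = -65.0;
  double m0 = alpha_m(V0) / (alpha_m(V0) + beta_m(V0));
  double h0 = alpha_h(V0) / (alpha_h(V0) + beta_h(V0));
  double n0 = alpha_n(V0) / (alpha_n(V0) + beta_n(V0));

  std::vector<std::vector<double> > et(n_neurons), eg(n_neurons);
  for (int i = 0; i < event_time.size(); ++i) {
    int nb = event_neuron[i];
    if (nb < 0 || nb >= n_neurons) stop("event neuron index out of range");
    et[nb].push_back(event_time[i]);
    eg[nb].push_back(event_g[i]);
  }

  NumericVector first_spike(n_neurons, NA_REAL);
  IntegerVector n_spikes(n_neurons, 0);

  int nsteps = (int)std::ceil(t_end / dt);
  for (int nb = 0; nb < n_neurons; ++nb) {
    if (et[nb].empty()) continue;  // no input: stays at rest
    double V = V0, m = m0, h = h0, n = n0;
    bool armed = true;  // ready to register an upward threshold crossing
    double t = 0.0;
    for (int s = 0; s < nsteps; ++s) {
      double g1 = syn_g(t, et[nb], eg[nb], p.tau_syn);
      double g2 = syn_g(t + dt / 2.0, et[nb], eg[nb], p.tau_syn);
      double g3 = syn_g(t + dt, et[nb], eg[nb], p.tau_syn);
      Deriv k1 = hh_deriv(V, m, h, n, g1, p);
      Deriv k2 = hh_deriv(V + dt / 2 * k1.dV, m + dt / 2 * k1.dm,
                          h + dt / 2 * k1.dh, n + dt / 2 * k1.dn, g2, p);
      Deriv k3 = hh_deriv(V + dt / 2 * k2.dV, m + dt / 2 * k2.dm,
                          h + dt / 2 * k2.dh, n + dt / 2 * k2.dn, g2, p);
      Deriv k4 = hh_deriv(V + dt * k3.dV, m + dt * k3.dm,
                          h + dt * k3.dh, n + dt * k3.dn, g3, p);
      double Vn = V + dt / 6.0 * (k1.dV + 2 * k2.dV + 2 * k3.dV + k4.dV);
      m += dt / 6.0 * (k1.dm + 2 * k2.dm + 2 * k3.dm + k4.dm);
      h += dt / 6.0 * (k1.dh + 2 * k2.dh + 2 * k3.dh + k4.dh);
      n += dt / 6.0 * (k1.dn + 2 * k2.dn + 2 * k3.dn + k4.dn);
      if (armed && V < 0.0 && Vn >= 0.0) {
        double frac = (0.0 - V) / (Vn - V);
        double ts = t + frac * dt;
        if (n_spikes[nb] == 0) first_spike[nb] = ts;
        n_spikes[nb]++;
        armed = false;
      }
      if (!armed && Vn < -20.0) armed = true;
      V = Vn;
      t += dt;
    }
  }
  return List::create(Named("first_spike") = first_spike,
                      Named("n_spikes") = n_spikes);
}
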