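// Forward-Euler / Euler-Maruyama integrators for the memristor device law,
// the Hodgkin-Huxley neuron, the memristor-hybrid neuron and the
// multi-compartment axon.  Time is in ms, voltages in the units noted per
// routine, currents in uA (device) or uA/cm^2 (membrane).
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// sinh/exp arguments are clamped: |arg| <= 40 is far beyond any physical
// bias for these devices and keeps forward-Euler iterates finite.
static inline double clamp40(double x) {
  if (x > 40.0) return 40.0;
  if (x < -40.0) return -40.0;
  return x;
}

// p: tau alpha beta gamma delta eta lam wmin wmax
static inline double dev_i(const double* p, double w, double V, bool linear) {
  if (linear) {
    // linear-conductance variant: i = w (gamma*delta - alpha*beta) V + alpha*beta V
    return w * (p[3] * p[4] - p[1] * p[2]) * V + p[1] * p[2] * V;
  }
  return (1.0 - w) * p[1] * (1.0 - std::exp(-clamp40(p[2] * V)))
       + w * p[3] * std::sinh(clamp40(p[4] * V));
}

static inline double dev_window(double w) { return 1.0 - std::exp(w - 3.0); }

// window multiplies the potentiation term only
static inline double dev_rate(const double* p, double w, double V) {
  return dev_window(w) * p[6] * std::sinh(clamp40(p[5] * V)) - (w - p[7]) / p[0];
}

static inline double clampw(const double* p, double w) {
  if (w < p[7]) return p[7];
  if (w > p[8]) return p[8];
  return w;
}

// Device under a prescribed voltage waveform.  Returns w and i sampled at
// the same instants as V (state before the Euler update).
// [[Rcpp::export]]
List cpp_device_sim(NumericVector p, NumericVector V, double w0, double dt,
                    bool linear = false) {
  const double* pp = p.begin();
  int n = V.size();
  NumericVector w(n), i(n);
  double wc = clampw(pp, w0);
  for (int k = 0; k < n; ++k) {
    w[k] = wc;
    i[k] = dev_i(pp, wc, V[k], linear);
    wc = clampw(pp, wc + dt * dev_rate(pp, wc, V[k]));
  }
  return List::create(_["w"] = w, _["i"] = i);
}

// Reduced conductance model: dG/dt = -(G - Gmin)/tau + A * on(t)
// [[Rcpp::export]]
NumericVector cpp_reduced_sim(double tau, double A, double Gmin,
                              LogicalVector on, double dt, double G0) {
  int n = on.size();
  NumericVector G(n);
  double g = G0;
  for (int k = 0; k < n; ++k) {
    G[k] = g;
    g += dt * (-(g - Gmin) / tau + (on[k] ? A : 0.0));
  }
  return G;
}

static inline void hh_rates(double V, double* a, double* b) {
  // canonical squid-axon rate functions, modern convention (rest ~ -65 mV)
  double x;
  x = V + 55.0;  // alpha_n, removable singularity at x = 0
  a[0] = (std::fabs(x) < 1e-7) ? 0.1 : 0.01 * x / (1.0 - std::exp(-x / 10.0));
  b[0] = 0.125 * std::exp(-(V + 65.0) / 80.0);
  x = V + 40.0;  // alpha_m
  a[1] = (std::fabs(x) < 1e-7) ? 1.0 : 0.1 * x / (1.0 - std::exp(-x / 10.0));
  b[1] = 4.0 * std::exp(-(V + 65.0) / 18.0);
  a[2] = 0.07 * std::exp(-(V + 65.0) / 20.0);  // alpha_h
  b[2] = 1.0 / (1.0 + std::exp(-(V + 35.0) / 10.0));
}

// [[Rcpp::export]]
NumericMatrix cpp_gate_rates(NumericVector V) {
  int n = V.size();
  NumericMatrix out(n, 6);
  double a[3], b[3];
  for (int k = 0; k < n; ++k) {
    hh_rates(V[k], a, b);
    out(k, 0) = a[0]; out(k, 1) = b[0];
    out(k, 2) = a[1]; out(k, 3) = b[1];
    out(k, 4) = a[2]; out(k, 5) = b[2];
  }
  return out;
}

// hp: Cm gNa gK gL ENa EK EL
// [[Rcpp::export]]
NumericMatrix cpp_hh_sim(NumericVector hp, NumericVector iapp, double dt,
                         double V0, double n0, double m0, double h0) {
  int n = iapp.size();
  NumericMatrix out(n, 4);
  double V = V0, gn = n0, gm = m0, gh = h0;
  double a[3], b[3];
  for (int k = 0; k < n; ++k) {
    out(k, 0) = V; out(k, 1) = gn; out(k, 2) = gm; out(k, 3) = gh;
    hh_rates(V, a, b);
    double n4 = gn * gn * gn * gn;
    double m3 = gm * gm * gm;
    double dV = (iapp[k]
                 - hp[1] * m3 * gh * (V - hp[4])
                 - hp[2] * n4 * (V - hp[5])
                 - hp[3] * (V - hp[6])) / hp[0];
    V += dt * dV;
    gn += dt * (a[0] * (1.0 - gn) - b[0] * gn);
    gm += dt * (a[1] * (1.0 - gm) - b[1] * gm);
    gh += dt * (a[2] * (1.0 - gh) - b[2] * gh);
    if (gn < 0) gn = 0; else if (gn > 1) gn = 1;
    if (gm < 0) gm = 0; else if (gm > 1) gm = 1;
    if (gh < 0) gh = 0; else if (gh > 1) gh = 1;
  }
  return out;
}

// Hybrid neuron: K channel replaced by the scaled memristor.
// hp as above (gK unused), p device params, scales (Vs, Ts, Is).
// Columns: V m h w iK (iK in membrane units, uA/cm^2).
// [[Rcpp::export]]
NumericMatrix cpp_hybrid_sim(NumericVector hp, NumericVector p,
                             double Vs, double Ts, double Is,
                             NumericVector iapp, double dt,
                             double V0, double m0, double h0, double w0,
                             bool linear = false, double vmax = 500.0) {
  const double* pp = p.begin();
  int n = iapp.size();
  NumericMatrix out(n, 5);
  double V = V0, gm = m0, gh = h0, w = clampw(pp, w0);
  double a[3], b[3];
  int diverged = -1;
  for (int k = 0; k < n; ++k) {
    double Vdev = Vs * (V - hp[5]);           // device-side voltage, volts
    double iK = Is * dev_i(pp, w, Vdev, linear);
    out(k, 0) = V; out(k, 1) = gm; out(k, 2) = gh; out(k, 3) = w; out(k, 4) = iK;
    hh_rates(V, a, b);
    double m3 = gm * gm * gm;
    double dV = (iapp[k]
                 - hp[1] * m3 * gh * (V - hp[4])
                 - iK
                 - hp[3] * (V - hp[6])) / hp[0];
    V += dt * dV;
    gm += dt * (a[1] * (1.0 - gm) - b[1] * gm);
    gh += dt * (a[2] * (1.0 - gh) - b[2] * gh);
    w = clampw(pp, w + dt * Ts * dev_rate(pp, w, Vdev));
    if (gm < 0) gm = 0; else if (gm > 1) gm = 1;
    if (gh < 0) gh = 0; else if (gh > 1) gh = 1;
    if (!std::isfinite(V) || std::fabs(V) > vmax) { diverged = k; break; }
  }
  out.attr("diverged") = diverged;
  return out;
}

// Resistively coupled chain of hybrid compartments; sealed ends.
// Stimulus iapp goes to compartment `target` (0-based).  Voltage matrix is
// thinned by keep_every to bound memory.
// [[Rcpp::export]]
NumericMatrix cpp_axon_sim(NumericVector hp, NumericVector p,
                           double Vs, double Ts, double Is,
                           NumericVector iapp, double dt,
                           int ncomp, double gax, int target,
                           double V0, double m0, double h0, double w0,
                           bool linear = false, int keep_every = 1) {
  const double* pp = p.begin();
  int n = iapp.size();
  int nkeep = (n + keep_every - 1) / keep_every;
  NumericMatrix out(nkeep, ncomp);
  std::vector<double> V(ncomp, V0), gm(ncomp, m0), gh(ncomp, h0),
      w(ncomp, clampw(pp, w0)), Vnew(ncomp);
  double a[3], b[3];
  int row = 0;
  for (int k = 0; k < n; ++k) {
    if (k % keep_every == 0) {
      for (int j = 0; j < ncomp; ++j) out(row, j) = V[j];
      ++row;
    }
    for (int j = 0; j < ncomp; ++j) {
      double Vdev = Vs * (V[j] - hp[5]);
      double iK = Is * dev_i(pp, w[j], Vdev, linear);
      double icouple = 0.0;
      if (j > 0)         icouple += gax * (V[j - 1] - V[j]);
      if (j < ncomp - 1) icouple += gax * (V[j + 1] - V[j]);
      double ia = (j == target) ? iapp[k] : 0.0;
      hh_rates(V[j], a, b);
      double m3 = gm[j] * gm[j] * gm[j];
      double dV = (ia + icouple
                   - hp[1] * m3 * gh[j] * (V[j] - hp[4])
                   - iK
                   - hp[3] * (V[j] - hp[6])) / hp[0];
      Vnew[j] = V[j] + dt * dV;
      gm[j] += dt * (a[1] * (1.0 - gm[j]) - b[1] * gm[j]);
      gh[j] += dt * (a[2] * (1.0 - gh[j]) - b[2] * gh[j]);
      w[j] = clampw(pp, w[j] + dt * Ts * dev_rate(pp, w[j], Vdev));
      if (gm[j] < 0) gm[j] = 0; else if (gm[j] > 1) gm[j] = 1;
      if (gh[j] < 0) gh[j] = 0; else if (gh[j] > 1) gh[j] = 1;
    }
    std::swap(V, Vnew);
  }
  return out;
}
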