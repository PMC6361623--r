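#ifndef BLGAMMA_GATING_H
#define BLGAMMA_GATING_H

#include <cmath>
#include <vector>

// Voltage-dependent channel kinetics.  PN channels follow the published
// alpha/beta and x_inf/tau expressions; the A-type current and the
// fast-spiking interneuron spike currents are documented stand-ins
// (see the methods vignette).
//
// Channel codes:
//   1 na     PN transient Na (m^3 h)
//   2 dr     PN delayed rectifier (n)
//   3 m      PN muscarinic K (m^2)
//   4 ca     PN high-voltage-activated Ca (m^2 h)
//   5 nap    PN persistent Na (m)
//   6 a      PN A-type K stand-in (m h)
//   7 h      PN H current (single gate, opens with hyperpolarization)
//   8 sahp   PN Ca-dependent slow AHP (m; Ca-gated, no voltage table)
//   9 na_fs  FSI fast-spiking Na (m_inf^3 h), Wang-Buzsaki type, phi = 5
//  10 dr_fs  FSI fast-spiking delayed rectifier (n^4), phi = 5

namespace blg {

// x/(exp(x)-1) with removable singularity at 0
inline double exprel1(double x) {
  if (std::fabs(x) < 1e-7) return 1.0 - 0.5 * x;
  return x / (std::exp(x) - 1.0);
}

struct GateVal { double xinf, tau; };

inline GateVal pn_na_m(double v) {
  // alpha = -0.4(v+30)/(exp(-(v+30)/7.2)-1), beta = 0.124(v+30)/(exp((v+30)/7.2)-1)
  double a = 0.4 * 7.2 * exprel1(-(v + 30.0) / 7.2);
  double b = 0.124 * 7.2 * exprel1((v + 30.0) / 7.2);
  return { a / (a + b), 0.6156 / (a + b) };
}

inline GateVal pn_na_h(double v) {
  double a = 0.03 * 1.5 * exprel1(-(v + 45.0) / 1.5);
  double b = 0.01 * 1.5 * exprel1((v + 45.0) / 1.5);
  double xinf = 1.0 / (std::exp((v + 50.0) / 4.0) + 1.0);
  return { xinf, 0.6156 / (a + b) };
}

inline GateVal pn_dr_n(double v) {
  double a = std::exp(-0.1144 * (v + 15.0));
  double b = std::exp(-0.0801 * (v + 15.0));
  double xinf = 1.0 / (std::exp(-(v + 15.0) / 11.0) + 1.0);
  return { xinf, 50.0 * b / (1.0 + a) };
}

inline GateVal pn_m_m(double v) {
  double a = 0.016 * std::exp(-(v + 52.7) / 23.0);
  double b = 0.016 * std::exp((v + 52.7) / 18.8);
  double xinf = 1.0 / (std::exp(-(v + 52.7) / 10.3) + 1.0);
  return { xinf, 1.0 / (a + b) };
}

inline GateVal pn_ca_m(double v) {
  double xinf = 1.0 / (std::exp(-(v + 30.0) / 11.0) + 1.0);
  double tau = 2.5 / (std::exp(-(v + 37.1) / 32.3) + std::exp((v + 37.1) / 32.3));
  return { xinf, tau };
}

inline GateVal pn_ca_h(double v) {
  return { 1.0 / (std::exp((v + 12.6) / 18.9) + 1.0), 420.0 };
}

inline GateVal pn_nap_m(double v) {
  double xinf = 1.0 / (std::exp(-(v + 48.0) / 5.0) + 1.0);
  return { xinf, 2.5 + 14.0 * std::exp(-(v + 40.0) / 10.0) };
}

inline GateVal pn_a_m(double v) {   // stand-in
  return { 1.0 / (1.0 + std::exp(-(v + 50.0) / 10.0)), 2.0 };
}

inline GateVal pn_a_h(double v) {   // stand-in
  return { 1.0 / (1.0 + std::exp((v + 85.0) / 5.0)), 20.0 };
}

inline GateVal pn_h_q(double v) {
  double a = std::exp(0.0832 * (v + 75.0));
  double b = std::exp(0.0333 * (v + 75.0));
  double xinf = 1.0 / (std::exp((v + 81.0) / 8.0) + 1.0);
  return { xinf, b / (0.0081 * (1.0 + a)) };
}

// Ca-dependent sAHP gate: alpha = 0.0048/exp(-5*log10(Ca)-17.5),
// beta = 0.012/exp(2*log10(Ca)+20), tau = 48 ms.
inline GateVal pn_sahp_m(double ca, double floor_ca) {
  double c = ca > floor_ca ? ca : floor_ca;
  double L = std::log10(c);
  double a = 0.0048 / std::exp(-5.0 * L - 17.5);
  double b = 0.012 / std::exp(2.0 * L + 20.0);
  return { a / (a + b), 48.0 };
}

constexpr double FS_PHI = 5.0;
// fast-spiking kinetics shifted depolarized so the spike threshold sits
// near -45 mV (BLA fast-spiking cells; keeps the cell phasic under tonic
// synaptic drive)
constexpr double FS_SHIFT = 10.0;

inline GateVal fsi_na_m(double v0) {  // instantaneous activation
  double v = v0 - FS_SHIFT;
  double a = 0.1 * 10.0 * exprel1(-(v + 35.0) / 10.0);
  double b = 4.0 * std::exp(-(v + 60.0) / 18.0);
  return { a / (a + b), 0.0 };
}

inline GateVal fsi_na_h(double v0) {
  double v = v0 - FS_SHIFT;
  double a = 0.07 * std::exp(-(v + 58.0) / 20.0);
  double b = 1.0 / (std::exp(-0.1 * (v + 28.0)) + 1.0);
  return { a / (a + b), 1.0 / (FS_PHI * (a + b)) };
}

inline GateVal fsi_dr_n(double v0) {
  double v = v0 - FS_SHIFT;
  double a = 0.01 * 10.0 * exprel1(-(v + 34.0) / 10.0);
  double b = 0.125 * std::exp(-(v + 44.0) / 80.0);
  return { a / (a + b), 1.0 / (FS_PHI * (a + b)) };
}

// channel structure: exponents and gate dispatch
struct ChanKin {
  int p;          // activation exponent
  int q;          // inactivation exponent (0 = none)
  bool m_inst;    // activation is instantaneous (x = x_inf(V))
  bool ca_gated;  // gate depends on [Ca], not V
  GateVal (*mfun)(double);
  GateVal (*hfun)(double);
};

inline ChanKin chan_kin(int code) {
  switch (code) {
    case 1:  return {3, 1, false, false, pn_na_m, pn_na_h};
    case 2:  return {1, 0, false, false, pn_dr_n, nullptr};
    case 3:  return {2, 0, false, false, pn_m_m, nullptr};
    case 4:  return {2, 1, false, false, pn_ca_m, pn_ca_h};
    case 5:  return {1, 0, false, false, pn_nap_m, nullptr};
    case 6:  return {1, 1, false, false, pn_a_m, pn_a_h};
    case 7:  return {1, 0, false, false, pn_h_q, nullptr};
    case 8:  return {1, 0, false, true,  nullptr, nullptr};
    case 9:  return {3, 1, true,  false, fsi_na_m, fsi_na_h};
    case 10: return {4, 0, false, false, fsi_dr_n, nullptr};
  }
  return {0, 0, false, false, nullptr, nullptr};
}

inline double ipow(double x, int p) {
  double r = 1.0;
  for (int i = 0; i < p; ++i) r *= x;
  return r;
}

// Lookup table over membrane potential for one gate: x_inf and the
// exponential-Euler decay factor exp(-dt/tau) (or tau itself for tables
// queried by the R-level gating interface).
struct GateTable {
  double vmin = 0, dv_inv = 0;
  int n = 0;
  // interleaved knots (x_inf, exp(-dt/tau)) so one lookup touches one or
  // two adjacent cache lines
  std::vector<double> knot;
  void build(GateVal (*f)(double), double dt, double vmin_, double vmax, double dv) {
    vmin = vmin_; dv_inv = 1.0 / dv;
    n = (int)((vmax - vmin_) / dv) + 1;
    knot.resize(2 * n);
    for (int i = 0; i < n; ++i) {
      GateVal g = f(vmin_ + i * dv);
      knot[2 * i] = g.xinf;
      knot[2 * i + 1] = g.tau > 0 ? std::exp(-dt / g.tau) : 0.0;
    }
  }
  inline void lookup(double v, double &xi, double &ef) const {
    double u = (v - vmin) * dv_inv;
    if (u <= 0.0) { xi = knot[0]; ef = knot[1]; return; }
    int i = (int)u;
    if (i >= n - 1) { xi = knot[2 * n - 2]; ef = knot[2 * n - 1]; return; }
    double w = u - i;
    const double *k = &knot[2 * i];
    xi = k[0] + w * (k[2] - k[0]);
    ef = k[1] + w * (k[3] - k[1]);
  }
};

} // namespace blg

#endif
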