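// Fixed-step (50 us) network integrator.
//
// Gating variables advance by exponential Euler using tabulated x_inf and
// exp(-dt/tau); the voltage step is implicit (backward Euler) across the
// coupled compartments of each cell, solved directly on the soma-rooted
// star topology.  Synapses use the ON-pulse receptor ODE with exact
// exponential updates over each step; inactive synapses (no transmitter,
// negligible open fraction) cost nothing and their short-term-plasticity
// state is advanced lazily in closed form when the next event arrives.

#include <Rcpp.h>
#ifdef __SSE2__
#include <xmmintrin.h>
#include <pmmintrin.h>
#endif
#include "rng.h"
#include "gating.h"

using namespace Rcpp;
using namespace blg;

namespace {

struct ChanInst {
  int comp;        // local compartment index
  int code;
  double g;        // absolute maximal conductance, uS
  double erev;
  int voff;        // offset of this channel's gating state within the cell
  int nstate;
  int p, q;
  bool m_inst, ca_gated;
  const GateTable *tm = nullptr, *th = nullptr;   // set after table build
};

struct Archetype {
  int ncomp = 0, nvar = 0;
  std::vector<double> C, gl, el, gax;   // nF, uS, mV, uS (to parent = soma)
  double cdt[8], glel[8], Ca_ef = 1.0, sahp_ef = 1.0;
  std::vector<ChanInst> chans;
  bool has_ca = false;
  int ca_comp = 0, ca_chan = -1;
  double ca_tau = 1000.0, ca_k = 0.0, ca_floor = 1e-10, ca_iconv = 0.0;
  int syn_exc = 0, syn_inh = 0;
  // OU background (uS), exact-discretization constants
  double ge0 = 0, gi0 = 0, e_fac = 1, i_fac = 1, e_amp = 0, i_amp = 0;
};

struct SynClass {
  int kind;                       // 0 excitatory (AMPA+NMDA), 1 inhibitory
  double e_on1, rinf1, e_off1, g1;
  double e_on2, rinf2, e_off2, g2;
  bool stp;
  double dec1, dec2, sd1, sd2, dmin;
  double decf, sf;                // facilitation (sf = 1 disables)
};

inline double mg_block_s(double v) {
  return 1.0 / (1.0 + 0.33 * std::exp(-0.06 * v));
}

Archetype parse_archetype(List a) {
  Archetype ar;
  ar.C = as<std::vector<double>>(a["c_nF"]);
  ar.gl = as<std::vector<double>>(a["gl_uS"]);
  ar.el = as<std::vector<double>>(a["el"]);
  ar.gax = as<std::vector<double>>(a["gax_uS"]);
  ar.ncomp = (int)ar.C.size();
  List ch = a["channels"];
  IntegerVector ccomp = ch["comp"], ccode = ch["code"];
  NumericVector cg = ch["g_uS"], ce = ch["erev"];
  int off = 0;
  for (int i = 0; i < ccomp.size(); ++i) {
    ChanInst ci;
    ci.comp = ccomp[i]; ci.code = ccode[i];
    ci.g = cg[i]; ci.erev = ce[i];
    ChanKin k = chan_kin(ci.code);
    ci.p = k.p; ci.q = k.q; ci.m_inst = k.m_inst; ci.ca_gated = k.ca_gated;
    ci.nstate = (k.m_inst ? 0 : 1) + (k.q > 0 ? 1 : 0);
    ci.voff = off; off += ci.nstate;
    ar.chans.push_back(ci);
  }
  ar.nvar = off;
  List ca = a["ca"];
  ar.has_ca = as<int>(ca["has"]) != 0;
  if (ar.has_ca) {
    ar.ca_comp = as<int>(ca["comp"]);
    ar.ca_tau = as<double>(ca["tau"]);
    ar.ca_k = as<double>(ca["k"]);
    ar.ca_floor = as<double>(ca["floor"]);
    ar.ca_iconv = as<double>(ca["iconv"]);  // nA -> mA/cm2 at the Ca compartment
    for (size_t i = 0; i < ar.chans.size(); ++i)
      if (ar.chans[i].code == 4 && ar.chans[i].comp == ar.ca_comp) ar.ca_chan = (int)i;
  }
  ar.syn_exc = as<int>(a["syn_exc"]);
  ar.syn_inh = as<int>(a["syn_inh"]);
  List ou = a["ou"];
  double dt = as<double>(a["dt"]);
  double ge0 = as<double>(ou["ge0"]), ge_sd = as<double>(ou["ge_sd"]),
         taue = as<double>(ou["taue"]), gi0 = as<double>(ou["gi0"]),
         gi_sd = as<double>(ou["gi_sd"]), taui = as<double>(ou["taui"]);
  ar.ge0 = ge0; ar.gi0 = gi0;
  ar.e_fac = std::exp(-dt / taue);
  ar.i_fac = std::exp(-dt / taui);
  ar.e_amp = ge_sd * std::sqrt(1.0 - ar.e_fac * ar.e_fac);
  ar.i_amp = gi_sd * std::sqrt(1.0 - ar.i_fac * ar.i_fac);
  for (int k = 0; k < ar.ncomp; ++k) {
    ar.cdt[k] = ar.C[k] / dt;
    ar.glel[k] = ar.gl[k] * ar.el[k];
  }
  ar.Ca_ef = std::exp(-dt / ar.ca_tau);
  ar.sahp_ef = std::exp(-dt / 48.0);
  return ar;
}

} // namespace

// [[Rcpp::export]]
List cpp_simulate(List net) {
#ifdef __SSE2__
  // flush denormals: decaying gating/receptor residuals otherwise hit
  // subnormal microcode assists and dominate the run time
  unsigned int csr_save = _mm_getcsr();
  _MM_SET_FLUSH_ZERO_MODE(_MM_FLUSH_ZERO_ON);
  _MM_SET_DENORMALS_ZERO_MODE(_MM_DENORMALS_ZERO_ON);
#endif
  const double dt = as<double>(net["dt"]);
  const long n_steps = (long)as<double>(net["n_steps"]);
  const int steps_per_ms = (int)std::lround(1.0 / dt);
  const uint64_t seed = (uint64_t)as<double>(net["seed"]);
  const int on_steps_full = (int)std::lround(as<double>(net["on_ms"]) / dt);

  IntegerVector types = net["types"];           // 0-based archetype per cell
  const int ncell = types.size();

  List arch_list = net["archetypes"];
  std::vector<Archetype> arch;
  for (int i = 0; i < arch_list.size(); ++i)
    arch.push_back(parse_archetype(arch_list[i]));

  // gating tables per channel code (direct-indexed)
  const int NCODE = 16;
  std::vector<GateTable> tab_m(NCODE), tab_h(NCODE);
  std::vector<bool> tab_built(NCODE, false);
  for (auto &ar : arch) for (auto &ci : ar.chans) {
    if (tab_built[ci.code]) continue;
    ChanKin k = chan_kin(ci.code);
    if (!k.ca_gated) {
      tab_m[ci.code].build(k.mfun, dt, -130.0, 70.0, 0.25);
      if (k.q > 0) tab_h[ci.code].build(k.hfun, dt, -130.0, 70.0, 0.25);
    }
    tab_built[ci.code] = true;
  }
  for (auto &ar : arch) for (auto &ci : ar.chans) {
    ci.tm = &tab_m[ci.code]; ci.th = &tab_h[ci.code];
  }

  // global compartment / gating-state offsets
  std::vector<int> comp_off(ncell + 1, 0), var_off(ncell + 1, 0);
  for (int c = 0; c < ncell; ++c) {
    comp_off[c + 1] = comp_off[c] + arch[types[c]].ncomp;
    var_off[c + 1] = var_off[c] + arch[types[c]].nvar;
  }
  const int ncomp_tot = comp_off[ncell];

  // synapse classes
  List cls_list = net["classes"];
  std::vector<SynClass> cls;
  for (int i = 0; i < cls_list.size(); ++i) {
    List c = cls_list[i];
    SynClass s;
    s.kind = as<int>(c["kind"]);
    s.e_on1 = as<double>(c["e_on1"]); s.rinf1 = as<double>(c["rinf1"]);
    s.e_off1 = as<double>(c["e_off1"]); s.g1 = as<double>(c["g1_uS"]);
    s.e_on2 = as<double>(c["e_on2"]); s.rinf2 = as<double>(c["rinf2"]);
    s.e_off2 = as<double>(c["e_off2"]); s.g2 = as<double>(c["g2_uS"]);
    s.stp = as<int>(c["stp"]) != 0;
    s.dec1 = as<double>(c["dec1"]); s.dec2 = as<double>(c["dec2"]);
    s.sd1 = as<double>(c["sd1"]); s.sd2 = as<double>(c["sd2"]);
    s.dmin = as<double>(c["dmin"]);
    s.decf = as<double>(c["decf"]); s.sf = as<double>(c["sf"]);
    cls.push_back(s);
  }

  // synapses (intrinsic edges then afferent edges share the state arrays)
  List edges = net["edges"];
  IntegerVector e_src = edges["src"], e_dst = edges["dst"],
                e_cls = edges["cls"], e_del = edges["delay_steps"];
  NumericVector e_w1 = edges["w1"], e_w2 = edges["w2"];
  List aff = net["aff_edges"];
  IntegerVector a_src = aff["aff"], a_dst = aff["dst"],
                a_cls = aff["cls"], a_del = aff["delay_steps"];
  NumericVector a_w1 = aff["w1"], a_w2 = aff["w2"];
  const int n_int = e_src.size(), n_aff_syn = a_src.size();
  const int nsyn = n_int + n_aff_syn;

  std::vector<int> s_dstcomp(nsyn), s_cls(nsyn), s_del(nsyn);
  std::vector<double> s_w1(nsyn), s_w2(nsyn);
  std::vector<double> s_r1(nsyn, 0.0), s_r2(nsyn, 0.0),
                      s_d1(nsyn, 1.0), s_d2(nsyn, 1.0), s_F(nsyn, 1.0),
                      s_mult(nsyn, 1.0);
  std::vector<int> s_on(nsyn, 0);
  std::vector<long> s_last(nsyn, 0), s_dlast(nsyn, 0);
  std::vector<uint8_t> s_active(nsyn, 0);

  int max_del = 1;
  for (int i = 0; i < nsyn; ++i) {
    bool intr = i < n_int;
    int dst = intr ? e_dst[i] : a_dst[i - n_int];      // 0-based cell
    int c = intr ? e_cls[i] : a_cls[i - n_int];        // 0-based class
    const Archetype &ad = arch[types[dst]];
    int local = (cls[c].kind == 0) ? ad.syn_exc : ad.syn_inh;
    s_dstcomp[i] = comp_off[dst] + local;
    s_cls[i] = c;
    s_del[i] = intr ? e_del[i] : a_del[i - n_int];
    s_w1[i] = intr ? e_w1[i] : a_w1[i - n_int];
    s_w2[i] = intr ? e_w2[i] : a_w2[i - n_int];
    if (s_del[i] < 1) s_del[i] = 1;
    if (s_del[i] > max_del) max_del = s_del[i];
  }

  // outgoing CSR for cells and afferents
  std::vector<int> out_off(ncell + 1, 0), out_idx(n_int);
  for (int i = 0; i < n_int; ++i) out_off[e_src[i] + 1]++;
  for (int c = 0; c < ncell; ++c) out_off[c + 1] += out_off[c];
  { std::vector<int> cur(out_off.begin(), out_off.end() - 1);
    for (int i = 0; i < n_int; ++i) out_idx[cur[e_src[i]]++] = i; }
  int n_aff = as<int>(net["n_afferents"]);
  std::vector<int> aout_off(n_aff + 1, 0), aout_idx(n_aff_syn);
  for (int i = 0; i < n_aff_syn; ++i) aout_off[a_src[i] + 1]++;
  for (int c = 0; c < n_aff; ++c) aout_off[c + 1] += aout_off[c];
  { std::vector<int> cur(aout_off.begin(), aout_off.end() - 1);
    for (int i = 0; i < n_aff_syn; ++i) aout_idx[cur[a_src[i]]++] = i + n_int; }

  // afferent spike times (flattened, sorted within each afferent)
  NumericVector aff_t = net["aff_times"];
  IntegerVector aff_ptr0 = net["aff_offsets"];   // length n_aff+1, 0-based
  std::vector<long> aff_ptr(n_aff);
  for (int i = 0; i < n_aff; ++i) aff_ptr[i] = aff_ptr0[i];

  // gap junctions
  List gaps = net["gaps"];
  IntegerVector g_a = gaps["a"], g_b = gaps["b"];
  NumericVector g_g = gaps["g_uS"];
  const int ngap = g_a.size();

  // current injections
  List inj = net["inj"];
  IntegerVector j_cell = inj["cell"], j_comp = inj["comp"];
  NumericVector j_s0 = inj["step0"], j_s1 = inj["step1"], j_amp = inj["amp_nA"];
  const int ninj = j_cell.size();

  // voltage clamp (true somatic clamp)
  List clamp = net["clamp"];
  IntegerVector cl_cell = clamp["cell"];
  NumericVector cl_hold = clamp["hold"];
  std::vector<double> hold_of(ncell, NA_REAL);
  std::vector<uint8_t> clamped(ncell, 0);
  for (int i = 0; i < cl_cell.size(); ++i) {
    clamped[cl_cell[i]] = 1; hold_of[cl_cell[i]] = cl_hold[i];
  }
  const int nclamp = cl_cell.size();

  // recorders
  IntegerVector rec_v = net["record_v"];             // 0-based cells
  const bool v_every_step = as<bool>(net["v_every_step"]);
  IntegerVector vc_cells = net["vc_cells"];          // shadow PSC recorders
  const bool rec_imem = as<bool>(net["record_imem"]);
  NumericMatrix lfp_coef = net["lfp_coef"];          // ncomp_tot x nelec (0x0 = off)
  const int nelec = lfp_coef.ncol();
  const bool audit = as<bool>(net["audit"]);

  const long n_ms = n_steps / steps_per_ms;
  const int nrec = rec_v.size(), nvc = vc_cells.size();
  NumericMatrix v_out(v_every_step ? n_steps : n_ms, nrec);
  NumericMatrix epsc(n_ms, nvc), ipsc(n_ms, nvc);
  NumericMatrix lfp(nelec > 0 ? n_ms : 0, nelec);
  NumericMatrix imem_out(rec_imem ? n_ms : 0, rec_imem ? ncomp_tot : 0);
  NumericMatrix clamp_out(n_ms, nclamp);
  NumericMatrix ca_out(n_ms, nrec);
  std::vector<double> epsc_acc(nvc, 0.0), ipsc_acc(nvc, 0.0), clamp_acc(nclamp, 0.0);

  // state
  std::vector<double> V(ncomp_tot), gvar(var_off[ncell]);
  std::vector<double> Ca(ncell, 0.0);
  std::vector<double> ge(ncell), gi(ncell);
  std::vector<Rng> rng(ncell);
  std::vector<long> last_spike(ncell, -1000000);
  for (int c = 0; c < ncell; ++c) {
    const Archetype &ar = arch[types[c]];
    for (int k = 0; k < ar.ncomp; ++k) V[comp_off[c] + k] = ar.el[k];
    for (auto &ci : ar.chans) {
      ChanKin kin = chan_kin(ci.code);
      double v0 = ar.el[ci.comp];
      int off = var_off[c] + ci.voff, p = 0;
      if (kin.ca_gated) {
        gvar[off] = pn_sahp_m(ar.ca_floor, ar.ca_floor).xinf;
        continue;
      }
      if (!kin.m_inst) gvar[off + p++] = kin.mfun(v0).xinf;
      if (kin.q > 0) gvar[off + p] = kin.hfun(v0).xinf;
    }
    Ca[c] = ar.has_ca ? ar.ca_floor : 0.0;
    ge[c] = ar.ge0; gi[c] = ar.gi0;
    if (clamped[c]) V[comp_off[c]] = hold_of[c];
    rng[c].seed(seed, (uint64_t)c);
  }

  // per-step synaptic conductance accumulators (uS)
  std::vector<double> Ga(ncomp_tot, 0.0), Gn(ncomp_tot, 0.0), Gg(ncomp_tot, 0.0);
  // decay pools: summed w * mult * r of all synapses past their transmitter
  // pulse, per (class, compartment); each pool decays by its class's
  // exp(-beta dt) every step, so closed tails cost O(classes x comps)
  const int ncls = (int)cls.size();
  std::vector<std::vector<double>> pool1(ncls), pool2(ncls);
  for (int c = 0; c < ncls; ++c) {
    pool1[c].assign(ncomp_tot, 0.0);
    pool2[c].assign(ncomp_tot, 0.0);
  }
  std::vector<double> gap_rhs(ncell, 0.0);
  std::vector<double> imem(ncomp_tot, 0.0), imem_acc(ncomp_tot, 0.0);
  std::vector<double> inj_now(ncomp_tot, 0.0);

  // delayed event ring
  const int ring_len = max_del + 1;
  std::vector<std::vector<int>> ring(ring_len);
  std::vector<int> active; active.reserve(nsyn);

  std::vector<int> spk_cell; std::vector<double> spk_t;
  const double spike_thresh = as<double>(net["spike_threshold"]);
  const long refrac_steps = (long)std::lround(as<double>(net["refractory_ms"]) / dt);
  const double s_epsc_hold = mg_block_s(-75.0);
  double audit_max = 0.0;
  bool blew_up = false; int blew_cell = -1;

  // scratch for the per-cell solve
  std::vector<double> diagv(8), rhsv(8), Gsum(8), Esum(8), voldv(8), gsynv(8), esynv(8);

  auto stp_event = [&](int sid, long step) {
    const SynClass &sc = cls[s_cls[sid]];
    const int c = s_cls[sid], dc = s_dstcomp[sid];
    if (!s_active[sid]) {
      // advance the lazily-decayed open fractions and withdraw this
      // synapse's tail from the pools before re-opening it
      double gap = (double)(step - s_last[sid]);
      s_r1[sid] *= std::pow(sc.e_off1, gap);
      pool1[c][dc] -= s_w1[sid] * s_mult[sid] * s_r1[sid];
      if (sc.g2 > 0) {
        s_r2[sid] *= std::pow(sc.e_off2, gap);
        pool2[c][dc] -= s_w2[sid] * s_r2[sid];
      }
    }
    if (sc.stp) {
      double dgap = (double)(step - s_dlast[sid]);
      s_d1[sid] = 1.0 + (s_d1[sid] - 1.0) * std::pow(sc.dec1, dgap);
      s_d2[sid] = 1.0 + (s_d2[sid] - 1.0) * std::pow(sc.dec2, dgap);
      s_d1[sid] *= sc.sd1;
      s_d2[sid] *= sc.sd2;
      double D = s_d1[sid] * s_d2[sid];
      if (D < sc.dmin) D = sc.dmin;
      double F = 1.0;
      if (sc.sf != 1.0) {
        s_F[sid] = 1.0 + (s_F[sid] - 1.0) * std::pow(sc.decf, dgap);
        s_F[sid] *= sc.sf;
        F = s_F[sid];
      }
      s_mult[sid] = F * D;
      s_dlast[sid] = step;
    }
    s_on[sid] = on_steps_full;
    if (!s_active[sid]) { s_active[sid] = 1; active.push_back(sid); }
    s_last[sid] = step;
  };

  double *__restrict Vp = V.data();
  double *__restrict gvp = gvar.data();
  double *__restrict Gap = Ga.data();
  double *__restrict Gnp = Gn.data();
  double *__restrict Ggp = Gg.data();
  double *__restrict injp = inj_now.data();
  double *__restrict gapp = gap_rhs.data();
  double *__restrict imemp = imem.data();
  double *__restrict Cap = Ca.data();
  double *__restrict gep = ge.data();
  double *__restrict gip = gi.data();
  for (long step = 0; step < n_steps; ++step) {
    const double t = step * dt;
    const int slot = (int)(step % ring_len);

    // (1) afferent spikes this step -> enqueue their synapses
    for (int a2 = 0; a2 < n_aff; ++a2) {
      while (aff_ptr[a2] < aff_ptr0[a2 + 1] && aff_t[aff_ptr[a2]] < t + dt) {
        for (int k = aout_off[a2]; k < aout_off[a2 + 1]; ++k) {
          int sid = aout_idx[k];
          ring[(step + s_del[sid]) % ring_len].push_back(sid);
        }
        aff_ptr[a2]++;
      }
    }

    // (2) deliver events due now
    for (int sid : ring[slot]) stp_event(sid, step);
    ring[slot].clear();

    // (3) decay the tail pools, advance ON-phase synapses, accumulate
    // conductances
    std::fill(Ga.begin(), Ga.end(), 0.0);
    std::fill(Gn.begin(), Gn.end(), 0.0);
    std::fill(Gg.begin(), Gg.end(), 0.0);
    for (int c = 0; c < ncls; ++c) {
      const SynClass &sc = cls[c];
      double *p1 = pool1[c].data(), *p2 = pool2[c].data();
      if (sc.kind == 0) {
        for (int k = 0; k < ncomp_tot; ++k) {
          p1[k] *= sc.e_off1;
          if (p1[k] > 0) Gap[k] += sc.g1 * p1[k];
          if (sc.g2 > 0) {
            p2[k] *= sc.e_off2;
            if (p2[k] > 0) Gnp[k] += sc.g2 * p2[k];
          }
        }
      } else {
        for (int k = 0; k < ncomp_tot; ++k) {
          p1[k] *= sc.e_off1;
          if (p1[k] > 0) Ggp[k] += sc.g1 * p1[k];
        }
      }
    }
    size_t keep = 0;
    for (size_t ii = 0; ii < active.size(); ++ii) {
      int sid = active[ii];
      const SynClass &sc = cls[s_cls[sid]];
      double r1 = sc.rinf1 + (s_r1[sid] - sc.rinf1) * sc.e_on1;
      double r2 = s_r2[sid];
      if (sc.g2 > 0) r2 = sc.rinf2 + (r2 - sc.rinf2) * sc.e_on2;
      s_r1[sid] = r1; s_r2[sid] = r2;
      s_on[sid]--;
      s_last[sid] = step;
      int dc = s_dstcomp[sid];
      double c1 = sc.g1 * s_w1[sid] * s_mult[sid] * r1;
      if (sc.kind == 0) {
        Gap[dc] += c1;
        if (sc.g2 > 0) Gnp[dc] += sc.g2 * s_w2[sid] * r2;
      } else {
        Ggp[dc] += c1;
      }
      if (s_on[sid] == 0) {
        // transmitter pulse over: fold the tail into the pools
        int c = s_cls[sid];
        pool1[c][dc] += s_w1[sid] * s_mult[sid] * r1;
        if (sc.g2 > 0) pool2[c][dc] += s_w2[sid] * r2;
        s_active[sid] = 0;
      } else {
        active[keep++] = sid;
      }
    }
    active.resize(keep);

    // (4) gap junction currents (explicit, from previous-step voltages)
    std::fill(gap_rhs.begin(), gap_rhs.end(), 0.0);
    for (int g = 0; g < ngap; ++g) {
      double ia = g_g[g] * (Vp[comp_off[g_b[g]]] - Vp[comp_off[g_a[g]]]);
      gapp[g_a[g]] += ia;
      gapp[g_b[g]] -= ia;
    }

    // (5) injected currents
    std::fill(inj_now.begin(), inj_now.end(), 0.0);
    for (int j = 0; j < ninj; ++j)
      if (step >= (long)j_s0[j] && step < (long)j_s1[j])
        injp[comp_off[j_cell[j]] + j_comp[j]] += j_amp[j];

    // (6) per-cell update
    for (int c = 0; c < ncell; ++c) {
      const Archetype &ar = arch[types[c]];
      const int c0 = comp_off[c];

      // OU background (exact discretization), applied at the soma
      double gec = ar.ge0 + (gep[c] - ar.ge0) * ar.e_fac + ar.e_amp * rng[c].norm();
      double gic = ar.gi0 + (gip[c] - ar.gi0) * ar.i_fac + ar.i_amp * rng[c].norm();
      gep[c] = gec; gip[c] = gic;
      double ge_use = gec > 0 ? gec : 0.0, gi_use = gic > 0 ? gic : 0.0;

      // gating update + channel conductances
      for (int k = 0; k < ar.ncomp; ++k) { Gsum[k] = 0.0; Esum[k] = 0.0; }
      for (const auto &ci : ar.chans) {
        double v = Vp[c0 + ci.comp];
        int off = var_off[c] + ci.voff;
        double m, h = 1.0;
        if (ci.ca_gated) {
          // x_inf = 1 / (1 + (beta0/alpha0) Ca^{-7/ln10}); tau fixed
          double cca = Cap[c] > ar.ca_floor ? Cap[c] : ar.ca_floor;
          double xinf = 1.0 / (1.0 + 2.5 * std::exp(-37.5) * std::pow(cca, -7.0 / 2.302585092994046));
          gvp[off] = xinf + (gvp[off] - xinf) * ar.sahp_ef;
          m = gvp[off];
        } else if (ci.m_inst) {
          double xi, efd;
          ci.tm->lookup(v, xi, efd);
          m = xi;
          if (ci.q > 0) {
            ci.th->lookup(v, xi, efd);
            gvp[off] = xi + (gvp[off] - xi) * efd;
            h = gvp[off];
          }
        } else {
          double xi, efd;
          ci.tm->lookup(v, xi, efd);
          gvp[off] = xi + (gvp[off] - xi) * efd;
          m = gvp[off];
          if (ci.q > 0) {
            ci.th->lookup(v, xi, efd);
            gvp[off + 1] = xi + (gvp[off + 1] - xi) * efd;
            h = gvp[off + 1];
          }
        }
        double gg = ci.g * ipow(m, ci.p) * (ci.q > 0 ? h : 1.0);
        Gsum[ci.comp] += gg;
        Esum[ci.comp] += gg * ci.erev;
      }

      // assemble and solve the implicit voltage step
      for (int k = 0; k < ar.ncomp; ++k) {
        int gc = c0 + k;
        voldv[k] = Vp[gc];
        double Gtot = ar.gl[k] + Gsum[k];
        double rhs = ar.cdt[k] * Vp[gc] + ar.glel[k] + Esum[k] + injp[gc];
        double Gsyn = Gap[gc] + Ggp[gc];
        if (Gnp[gc] > 0) Gsyn += Gnp[gc] * mg_block_s(Vp[gc]);
        double Esyn = Ggp[gc] * (-75.0);     // GABA reversal; AMPA/NMDA at 0 mV
        if (k == 0) {
          Gsyn += ge_use + gi_use;
          Esyn += gi_use * (-75.0);
          rhs += gapp[c];
        }
        gsynv[k] = Gsyn; esynv[k] = Esyn;
        rhs += Esyn;
        Gtot += Gsyn;
        diagv[k] = ar.cdt[k] + Gtot;
        rhsv[k] = rhs;
      }
      // children (k >= 1) all attach to the soma (k = 0)
      if (!clamped[c]) {
        double dsoma = diagv[0], rsoma = rhsv[0];
        double invdk[8];
        for (int k = 1; k < ar.ncomp; ++k) {
          double g = ar.gax[k];
          invdk[k] = 1.0 / (diagv[k] + g);
          dsoma += g - g * g * invdk[k];
          rsoma += g * rhsv[k] * invdk[k];
        }
        double vs = rsoma / dsoma;
        double vold0 = Vp[c0];
        Vp[c0] = vs;
        for (int k = 1; k < ar.ncomp; ++k)
          Vp[c0 + k] = (rhsv[k] + ar.gax[k] * vs) * invdk[k];
        // spike detection at the soma
        if (vold0 < spike_thresh && vs >= spike_thresh &&
            step - last_spike[c] > refrac_steps) {
          last_spike[c] = step;
          spk_cell.push_back(c);
          spk_t.push_back(t + dt);
          for (int k = out_off[c]; k < out_off[c + 1]; ++k) {
            int sid = out_idx[k];
            ring[(step + s_del[sid]) % ring_len].push_back(sid);
          }
        }
      } else {
        double vh = hold_of[c];
        Vp[c0] = vh;
        double axial_to_soma = 0.0;
        for (int k = 1; k < ar.ncomp; ++k) {
          double g = ar.gax[k];
          Vp[c0 + k] = (rhsv[k] + g * vh) / (diagv[k] + g);
          axial_to_soma += g * (Vp[c0 + k] - vh);
        }
        // electrode current required to hold the soma (positive outward)
        double i_cl = (diagv[0] - ar.C[0] / dt) * vh - (rhsv[0] - ar.C[0] / dt * vh)
                      - axial_to_soma;
        for (int q = 0; q < nclamp; ++q)
          if (cl_cell[q] == c) clamp_acc[q] += i_cl;
      }

      // transmembrane current per compartment (outward positive):
      // equals net axial input + injections (+ gap-junction input at the soma)
      {
        double ax0 = 0.0;
        for (int k = 1; k < ar.ncomp; ++k) {
          double g = ar.gax[k];
          double axk = g * (Vp[c0] - Vp[c0 + k]);
          imemp[c0 + k] = axk + injp[c0 + k];
          ax0 -= axk;
        }
        imemp[c0] = ax0 + injp[c0] + gapp[c];
      }

      // Ca pool (uses updated gating and voltage)
      if (ar.has_ca && ar.ca_chan >= 0) {
        const ChanInst &ci = ar.chans[ar.ca_chan];
        int off = var_off[c] + ci.voff;
        double m = gvp[off], h = ci.q > 0 ? gvp[off + 1] : 1.0;
        double ica_nA = ci.g * ipow(m, ci.p) * h * (Vp[c0 + ci.comp] - ci.erev);
        double influx = -ar.ca_k * ica_nA * ar.ca_iconv;   // pool units / ms
        if (influx < 0) influx = 0;
        double targ = influx * ar.ca_tau;
        Cap[c] = targ + (Cap[c] - targ) * ar.Ca_ef;
        if (Cap[c] < 0) Cap[c] = 0;
      }

      if (audit && !clamped[c]) {
        // independent reconstruction of each compartment's transmembrane
        // current from its physical constituents at the updated state:
        // capacitive + leak + gated ionic + synaptic + background.
        // Must match the axially-derived source current used for the LFP.
        for (int k = 0; k < ar.ncomp; ++k) {
          int gc = c0 + k;
          double direct = ar.cdt[k] * (Vp[gc] - voldv[k])
            + ar.gl[k] * (Vp[gc] - ar.el[k])
            + Gsum[k] * Vp[gc] - Esum[k]
            + gsynv[k] * Vp[gc] - esynv[k];
          double d = std::fabs(direct - imemp[gc]);
          if (d > audit_max) audit_max = d;
        }
      }

      if (!std::isfinite(Vp[c0])) { blew_up = true; blew_cell = c; }
    }
    if (blew_up) break;

    // (7) recording
    for (int cidx = 0; cidx < ncomp_tot; ++cidx) imem_acc[cidx] += imemp[cidx];
    for (int q = 0; q < nvc; ++q) {
      int c = vc_cells[q], c02 = comp_off[c];
      const Archetype &ar = arch[types[c]];
      double ie = 0.0, ii = 0.0;
      for (int k = 0; k < ar.ncomp; ++k) {
        int gc = c02 + k;
        ie += (Gap[gc] + Gnp[gc] * s_epsc_hold) * (-75.0 - 0.0);
        ii += Ggp[gc] * (0.0 - (-75.0));
      }
      epsc_acc[q] += ie; ipsc_acc[q] += ii;
    }
    if (v_every_step)
      for (int q = 0; q < nrec; ++q) v_out(step, q) = Vp[comp_off[rec_v[q]]];

    if ((step + 1) % steps_per_ms == 0) {
      long row = (step + 1) / steps_per_ms - 1;
      double inv = 1.0 / steps_per_ms;
      if (!v_every_step)
        for (int q = 0; q < nrec; ++q) v_out(row, q) = Vp[comp_off[rec_v[q]]];
      for (int q = 0; q < nrec; ++q) ca_out(row, q) = Cap[rec_v[q]];
      for (int q = 0; q < nvc; ++q) {
        epsc(row, q) = epsc_acc[q] * inv; ipsc(row, q) = ipsc_acc[q] * inv;
        epsc_acc[q] = 0.0; ipsc_acc[q] = 0.0;
      }
      for (int q = 0; q < nclamp; ++q) {
        clamp_out(row, q) = clamp_acc[q] * inv; clamp_acc[q] = 0.0;
      }
      if (nelec > 0) {
        for (int e = 0; e < nelec; ++e) {
          double acc = 0.0;
          const double *col = &lfp_coef(0, e);
          for (int cidx = 0; cidx < ncomp_tot; ++cidx)
            acc += col[cidx] * imem_acc[cidx];
          lfp(row, e) = acc * inv;
        }
      }
      if (rec_imem)
        for (int cidx = 0; cidx < ncomp_tot; ++cidx)
          imem_out(row, cidx) = imem_acc[cidx] * inv;
      std::fill(imem_acc.begin(), imem_acc.end(), 0.0);
    }
  }

#ifdef __SSE2__
  _mm_setcsr(csr_save);
#endif
  if (blew_up)
    stop("non-finite membrane potential in cell %d; simulation aborted", blew_cell + 1);

  return List::create(
    _["spike_cell"] = wrap(spk_cell), _["spike_t"] = wrap(spk_t),
    _["v"] = v_out, _["epsc"] = epsc, _["ipsc"] = ipsc, _["ca"] = ca_out,
    _["lfp"] = lfp, _["imem"] = imem_out, _["clamp_i"] = clamp_out,
    _["audit_max"] = audit_max,
    _["final_v"] = wrap(V));
}

// Direct evaluation of the gating laws (used by the R-level gating
// interface only for the Ca-gated sAHP channel; voltage-gated channels are
// evaluated independently in R as an oracle for these C++ kinetics).
// [[Rcpp::export]]
List cpp_gating_eval(int code, NumericVector v, double ca, double ca_floor) {
  ChanKin k = chan_kin(code);
  int n = v.size();
  NumericVector m_inf(n), m_tau(n), h_inf(n), h_tau(n);
  for (int i = 0; i < n; ++i) {
    if (k.ca_gated) {
      GateVal g = pn_sahp_m(ca, ca_floor);
      m_inf[i] = g.xinf; m_tau[i] = g.tau;
    } else {
      GateVal g = k.mfun(v[i]);
      m_inf[i] = g.xinf; m_tau[i] = g.tau;
      if (k.q > 0) {
        GateVal gh = k.hfun(v[i]);
        h_inf[i] = gh.xinf; h_tau[i] = gh.tau;
      }
    }
  }
  return List::create(_["m_inf"] = m_inf, _["m_tau"] = m_tau,
                      _["h_inf"] = h_inf, _["h_tau"] = h_tau,
                      _["p"] = k.p, _["q"] = k.q, _["m_inst"] = k.m_inst);
}
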