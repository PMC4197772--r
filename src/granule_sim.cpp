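// Crank-Nicolson cable integration on a compartmental tree (Hines
// elimination), with Hodgkin-Huxley style channels, dual-exponential
// AMPA/NMDA synapses under magnesium block, spine-head calcium shells and
// exact (row-replacement) voltage clamps. All solver-internal quantities are
// SI (V, S, F, A, s); channel kinetics use mV/ms as is conventional.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// x / (1 - exp(-x/y)) with the removable singularity at x = 0
static inline double trap(double x, double y) {
  if (std::fabs(x / y) < 1e-6) return y * (1.0 + x / (2.0 * y));
  return x / (1.0 - std::exp(-x / y));
}

struct Kin {
  double vt_na, vt_k, km_vhalf, km_slope, km_taumax,
         kir_vhalf, kir_slope, kir_tau;
};

// gate rate/steady-state evaluations, V in mV, rates in 1/ms, tau in ms
static inline void na_m(double v, const Kin& k, double& inf, double& tau) {
  double a = 0.32 * trap(v - k.vt_na - 13.0, 4.0);
  double b = 0.28 * trap(-(v - k.vt_na - 40.0), 5.0);
  inf = a / (a + b); tau = 1.0 / (a + b);
}
static inline void na_h(double v, const Kin& k, double& inf, double& tau) {
  double a = 0.128 * std::exp(-(v - k.vt_na - 17.0) / 18.0);
  double b = 4.0 / (1.0 + std::exp(-(v - k.vt_na - 40.0) / 5.0));
  inf = a / (a + b); tau = 1.0 / (a + b);
}
static inline void kdr_n(double v, const Kin& k, double& inf, double& tau) {
  double a = 0.032 * trap(v - k.vt_k - 15.0, 5.0);
  double b = 0.5 * std::exp(-(v - k.vt_k - 10.0) / 40.0);
  inf = a / (a + b); tau = 1.0 / (a + b);
}
static inline void km_m(double v, const Kin& k, double& inf, double& tau) {
  inf = 1.0 / (1.0 + std::exp(-(v - k.km_vhalf) / k.km_slope));
  tau = k.km_taumax /
        (std::exp((v - k.km_vhalf) / 20.0) + std::exp(-(v - k.km_vhalf) / 20.0));
}
static inline void kir_a(double v, const Kin& k, double& inf, double& tau) {
  inf = 1.0 / (1.0 + std::exp((v - k.kir_vhalf) / k.kir_slope));
  tau = k.kir_tau;
}

static Kin kin_from(const NumericVector& kin) {
  Kin k;
  k.vt_na = kin["vt_na"]; k.vt_k = kin["vt_k"];
  k.km_vhalf = kin["km_vhalf"]; k.km_slope = kin["km_slope"];
  k.km_taumax = kin["km_taumax"];
  k.kir_vhalf = kin["kir_vhalf"]; k.kir_slope = kin["kir_slope"];
  k.kir_tau = kin["kir_tau"];
  return k;
}

// [[Rcpp::export]]
NumericMatrix cpp_gate_tables(NumericVector V_mV, NumericVector kin) {
  Kin k = kin_from(kin);
  int n = V_mV.size();
  NumericMatrix out(n, 10);
  colnames(out) = CharacterVector::create(
      "m_inf", "m_tau", "h_inf", "h_tau", "n_inf", "n_tau",
      "km_inf", "km_tau", "kir_inf", "kir_tau");
  for (int i = 0; i < n; ++i) {
    double v = V_mV[i], inf, tau;
    na_m(v, k, inf, tau);  out(i, 0) = inf; out(i, 1) = tau;
    na_h(v, k, inf, tau);  out(i, 2) = inf; out(i, 3) = tau;
    kdr_n(v, k, inf, tau); out(i, 4) = inf; out(i, 5) = tau;
    km_m(v, k, inf, tau);  out(i, 6) = inf; out(i, 7) = tau;
    kir_a(v, k, inf, tau); out(i, 8) = inf; out(i, 9) = tau;
  }
  return out;
}

static inline double dualexp_shape(double t, double tau1, double tau2,
                                   double norm) {
  if (t <= 0.0) return 0.0;
  return (std::exp(-t / tau2) - std::exp(-t / tau1)) / norm;
}

static inline double peak_norm(double tau1, double tau2) {
  double tstar = tau1 * tau2 * std::log(tau2 / tau1) / (tau2 - tau1);
  return std::exp(-tstar / tau2) - std::exp(-tstar / tau1);
}

// [[Rcpp::export]]
List cpp_simulate(List model, List protocol, List record,
                  double dt_ms, double t_end_ms, NumericVector v_init_mV) {
  const IntegerVector parent = model["parent"];        // 0-based, -1 root
  const NumericVector cm = model["cm"], g_pas = model["g_pas"],
                      e_pas = model["e_pas"], g_ax = model["g_ax"];
  const NumericMatrix gbar = model["gbar"];            // na kdr km kir (S)
  const double ena = model["ena"], ek = model["ek"];
  Kin kin = kin_from(model["kin"]);
  const int N = parent.size();
  const double dt = dt_ms / 1000.0;

  // synapses: unique heads + events referencing them
  const IntegerVector syn_heads = model["syn_heads"];  // 0-based comp ids
  const NumericMatrix events = model["events"];        // head_index, onset_s
  const int NH = syn_heads.size(), NE = events.nrow();
  List syn = model["syn"];
  const double a_gmax = syn["a_gmax"], a_tau1 = syn["a_tau1"],
               a_tau2 = syn["a_tau2"], a_E = syn["a_E"];
  const double n_gmax = syn["n_gmax"], n_tau1 = syn["n_tau1"],
               n_tau2 = syn["n_tau2"], n_E = syn["n_E"];
  const double eta = syn["eta"], mg = syn["mg"], gamma = syn["gamma"];
  const double a_norm = peak_norm(a_tau1, a_tau2),
               n_norm = peak_norm(n_tau1, n_tau2);
  List shell = model["shell"];
  const double sh_B = shell["B"], sh_r = shell["r"],
               sh_rest = shell["ca_rest"];
  List ghk = model["ghk"];
  const double cao = ghk["cao"], mono = ghk["monovalent"],
               prat = ghk["pratio"], TK = ghk["temperature"],
               FA = ghk["faraday"], RG = ghk["gas"];

  const NumericMatrix iclamp = protocol["iclamp"];  // comp amp on off
  const NumericMatrix vclamp = protocol["vclamp"];  // comp level on off

  const IntegerVector rec_sites = record["sites"];
  const CharacterVector rec_quant = record["quantities"];
  const int sample_every = record["sample_every"];
  const int NRS = rec_sites.size(), NRQ = rec_quant.size();

  // map comp -> head index for synaptic recorders
  std::vector<int> head_of(N, -1);
  for (int h = 0; h < NH; ++h) head_of[syn_heads[h]] = h;
  // quantity codes: 0 Vm, 1 G_AMPA, 2 G_NMDA, 3 I_NMDA, 4 Ca
  std::vector<int> qcode(NRQ);
  for (int q = 0; q < NRQ; ++q) {
    std::string s = as<std::string>(rec_quant[q]);
    qcode[q] = s == "Vm" ? 0 : s == "G_AMPA" ? 1 : s == "G_NMDA" ? 2 :
               s == "I_NMDA" ? 3 : s == "Ca" ? 4 : -1;
    if (qcode[q] < 0) stop("unknown recorded quantity: %s", s.c_str());
  }

  // state
  std::vector<double> V(N);
  for (int i = 0; i < N; ++i) V[i] = v_init_mV[i] / 1000.0;
  std::vector<double> gm(N), gh(N), gn(N), gkm(N), gkir(N);  // gate states
  for (int i = 0; i < N; ++i) {
    double v = V[i] * 1000.0, inf, tau;
    na_m(v, kin, inf, tau);  gm[i] = inf;
    na_h(v, kin, inf, tau);  gh[i] = inf;
    kdr_n(v, kin, inf, tau); gn[i] = inf;
    km_m(v, kin, inf, tau);  gkm[i] = inf;
    kir_a(v, kin, inf, tau); gkir[i] = inf;
  }
  std::vector<double> ca(NH, sh_rest);
  std::vector<double> gA(NH), gNbase(NH), gNeff(NH);

  // axial degree sums
  std::vector<double> gax_sum(N, 0.0);
  for (int i = 0; i < N; ++i) if (parent[i] >= 0) {
    gax_sum[i] += g_ax[i]; gax_sum[parent[i]] += g_ax[i];
  }
  // children lists for the explicit axial RHS term
  std::vector<std::vector<int> > children(N);
  for (int i = 0; i < N; ++i) if (parent[i] >= 0) children[parent[i]].push_back(i);

  const int nsteps = (int)std::llround(t_end_ms / dt_ms);
  const int nsamp = nsteps / sample_every + 1;
  NumericVector time_out(nsamp);
  NumericMatrix data(nsamp, NRS * NRQ);

  std::vector<double> dvec(N), rhs(N), b_up(N);
  std::vector<char> clamped(N);
  std::vector<double> active(N, 0.0);
  for (int i = 0; i < N; ++i)
    active[i] = gbar(i, 0) + gbar(i, 1) + gbar(i, 2) + gbar(i, 3);

  auto sample = [&](int srow, double t_ms) {
    time_out[srow] = t_ms;
    for (int s = 0; s < NRS; ++s) {
      int c = rec_sites[s], h = head_of[c];
      for (int q = 0; q < NRQ; ++q) {
        double val = NA_REAL;
        switch (qcode[q]) {
          case 0: val = V[c] * 1000.0; break;
          case 1: val = h >= 0 ? gA[h] * 1e9 : 0.0; break;
          case 2: val = h >= 0 ? gNeff[h] * 1e9 : 0.0; break;
          case 3: val = h >= 0 ? gNeff[h] * (n_E - V[c]) * 1e9 : 0.0; break;
          case 4: val = h >= 0 ? ca[h] : sh_rest; break;
        }
        data(srow, s * NRQ + q) = val;
      }
    }
  };
  sample(0, 0.0);

  for (int step = 0; step < nsteps; ++step) {
    const double t = step * dt;
    const double tmid = t + dt / 2.0;

    // 1. gates (exponential relaxation over dt at the current V)
    for (int i = 0; i < N; ++i) {
      if (active[i] <= 0.0) continue;
      double v = V[i] * 1000.0, inf, tau;
      if (gbar(i, 0) > 0) {
        na_m(v, kin, inf, tau); gm[i] = inf + (gm[i] - inf) * std::exp(-dt_ms / tau);
        na_h(v, kin, inf, tau); gh[i] = inf + (gh[i] - inf) * std::exp(-dt_ms / tau);
      }
      if (gbar(i, 1) > 0) {
        kdr_n(v, kin, inf, tau); gn[i] = inf + (gn[i] - inf) * std::exp(-dt_ms / tau);
      }
      if (gbar(i, 2) > 0) {
        km_m(v, kin, inf, tau); gkm[i] = inf + (gkm[i] - inf) * std::exp(-dt_ms / tau);
      }
      if (gbar(i, 3) > 0) {
        kir_a(v, kin, inf, tau); gkir[i] = inf + (gkir[i] - inf) * std::exp(-dt_ms / tau);
      }
    }

    // 2. synaptic conductances at midpoint time, block at current V
    for (int h = 0; h < NH; ++h) { gA[h] = 0.0; gNbase[h] = 0.0; }
    for (int e = 0; e < NE; ++e) {
      int h = (int)events(e, 0);
      double te = tmid - events(e, 1);
      if (te <= 0.0) continue;
      gA[h] += a_gmax * dualexp_shape(te, a_tau1, a_tau2, a_norm);
      gNbase[h] += n_gmax * dualexp_shape(te, n_tau1, n_tau2, n_norm);
    }
    for (int h = 0; h < NH; ++h) {
      double block = 1.0 / (1.0 + eta * mg * std::exp(-gamma * V[syn_heads[h]]));
      gNeff[h] = gNbase[h] * block;
    }

    // 3. assemble CN system
    for (int i = 0; i < N; ++i) {
      double gna = gbar(i, 0) * gm[i] * gm[i] * gm[i] * gh[i];
      double gk4 = gn[i] * gn[i]; gk4 *= gk4;
      double gkd = gbar(i, 1) * gk4;
      double gm_km = gbar(i, 2) * gkm[i];
      double gm_kir = gbar(i, 3) * gkir[i];
      double gmem = g_pas[i] + gna + gkd + gm_km + gm_kir;
      double src = g_pas[i] * e_pas[i] + gna * ena +
                   (gkd + gm_km + gm_kir) * ek;
      int h = head_of[i];
      if (h >= 0) {
        gmem += gA[h] + gNeff[h];
        src += gA[h] * a_E + gNeff[h] * n_E;
      }
      dvec[i] = cm[i] / dt + 0.5 * (gmem + gax_sum[i]);
      double axterm = 0.0;
      if (parent[i] >= 0) axterm += g_ax[i] * V[parent[i]];
      for (size_t cix = 0; cix < children[i].size(); ++cix) {
        int ch = children[i][cix];
        axterm += g_ax[ch] * V[ch];
      }
      rhs[i] = (cm[i] / dt - 0.5 * (gmem + gax_sum[i])) * V[i] +
               0.5 * axterm + src;
      b_up[i] = parent[i] >= 0 ? -0.5 * g_ax[i] : 0.0;
      clamped[i] = 0;
    }

    // current injections (mid-step value)
    for (int r = 0; r < iclamp.nrow(); ++r) {
      if (tmid >= iclamp(r, 2) && tmid < iclamp(r, 3))
        rhs[(int)iclamp(r, 0)] += iclamp(r, 1);
    }
    // voltage clamps: exact row replacement
    for (int r = 0; r < vclamp.nrow(); ++r) {
      double tn = t + dt;
      if (tn >= vclamp(r, 2) && tn <= vclamp(r, 3)) {
        int c = (int)vclamp(r, 0);
        dvec[c] = 1.0; b_up[c] = 0.0; rhs[c] = vclamp(r, 1);
        clamped[c] = 1;
      }
    }

    // 4. Hines solve (parents precede children in the ordering).
    // Row p's coefficient of V_i is -g_ax[i]/2 regardless of whether row i
    // was replaced by a clamp; clamped parent rows are left untouched.
    for (int i = N - 1; i >= 1; --i) {
      int p = parent[i];
      if (clamped[p]) continue;
      double f = (-0.5 * g_ax[i]) / dvec[i];
      dvec[p] -= f * b_up[i];
      rhs[p] -= f * rhs[i];
    }
    V[0] = rhs[0] / dvec[0];
    for (int i = 1; i < N; ++i)
      V[i] = (rhs[i] - b_up[i] * V[parent[i]]) / dvec[i];

    for (int i = 0; i < N; ++i)
      if (!std::isfinite(V[i]))
        stop("non-finite membrane potential at t = %f ms (compartment %d)",
             t * 1000.0, i + 1);

    // 5. calcium shells (exact relaxation, NMDA calcium fraction at new V)
    for (int h = 0; h < NH; ++h) {
      int c = syn_heads[h];
      double inmda = gNeff[h] * (n_E - V[c]);                  // A
      double expo = std::exp(2.0 * V[c] * FA / (RG * TK));
      double denom = cao + (1.0 / prat) * (mono / 4.0) * (1.0 - expo);
      double pf = denom <= 0.0 ? 0.0 : cao / denom;
      if (pf < 0.0) pf = 0.0; if (pf > 1.0) pf = 1.0;
      double influx = sh_B * (pf * inmda) * 1e3;               // uM/s
      double ca_inf = sh_rest + influx / sh_r;
      ca[h] = ca_inf + (ca[h] - ca_inf) * std::exp(-sh_r * dt);
      if (ca[h] < 0.0) ca[h] = 0.0;
    }

    if ((step + 1) % sample_every == 0)
      sample((step + 1) / sample_every, (step + 1) * dt_ms);
  }

  return List::create(_["time_ms"] = time_out, _["data"] = data);
}
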