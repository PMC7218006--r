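// Forward-Euler network engine for the thalamic alpha model.
//
// Cell types: 0 = HTC (high-threshold bursting thalamocortical pacemaker),
//             1 = TC  (relay), 2 = RE (reticular).
// All voltage-dependent kinetics follow the Traub/Destexhe-style forms used by
// the R-level reference functions in R/kinetics.R; the two must stay in sync
// (tested against each other).
#include <Rcpp.h>
#include <deque>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const double F_CA_ODE = 96489.0;   // Faraday constant as used in the Ca ODE
static const double RT2F_mV = 1000.0 * 8.314462618 * 309.15 / (2.0 * 96485.33212);

// x / (exp(x/y) - 1), with the removable singularity at x = 0 evaluated by limit
static inline double vtrap(double x, double y) {
  if (std::fabs(x / y) < 1e-6) return y * (1.0 - x / (2.0 * y));
  return x / (std::exp(x / y) - 1.0);
}

static inline double clamp01(double x) {
  return x < 0.0 ? 0.0 : (x > 1.0 ? 1.0 : x);
}

struct NaKRates {
  double an, bn, am, bm, ah, bh;
};

static inline NaKRates nak_rates(double vt) {
  NaKRates r;
  r.an = 0.032 * vtrap(15.0 - vt, 5.0);
  r.bn = 0.5 * std::exp((10.0 - vt) / 40.0);
  r.am = 0.32 * vtrap(13.0 - vt, 4.0);
  r.bm = 0.28 * vtrap(vt - 40.0, 5.0);
  r.ah = 0.128 * std::exp((17.0 - vt) / 18.0);
  r.bh = 4.0 / (std::exp((40.0 - vt) / 5.0) + 1.0);
  return r;
}

// Low-threshold T current (HTC and TC), voltage shifted by +2 mV
static inline double tlt_minf(double vt) { return 1.0 / (1.0 + std::exp(-(vt + 57.0) / 6.2)); }
static inline double tlt_hinf(double vt) { return 1.0 / (1.0 + std::exp((vt + 81.0) / 4.0)); }
static inline double tlt_tauh(double vt) {
  return (30.8 + (211.4 + std::exp((vt + 113.2) / 5.0)) /
                 (1.0 + std::exp((vt + 84.0) / 3.2))) / 3.74;
}

// High-threshold T current (HTC only), no voltage shift
static inline double tht_minf(double v) { return 1.0 / (1.0 + std::exp(-(v + 40.1) / 3.5)); }
static inline double tht_hinf(double v) { return 1.0 / (1.0 + std::exp((v + 62.2) / 5.5)); }
static inline double tht_tauh(double v) {
  return 0.1483 * std::exp(-0.09398 * v) + 5.284 * std::exp(0.008855 * v);
}

// HTC h-current gate
static inline double hr_inf(double v) { return 1.0 / (1.0 + std::exp((v + 60.0) / 5.5)); }
static inline double hr_tau(double v) {
  return 20.0 + 1000.0 / (std::exp((v + 56.5) / 14.2) + std::exp(-(v + 74.0) / 11.6));
}

// RE T current
static inline double tre_minf(double v) { return 1.0 / (1.0 + std::exp(-(v + 52.0) / 7.4)); }
static inline double tre_taum(double v) {
  return 0.99 + 0.333 / (std::exp((v + 27.0) / 10.0) + std::exp(-(v + 102.0) / 15.0));
}
static inline double tre_hinf(double v) { return 1.0 / (1.0 + std::exp((v + 80.0) / 5.0)); }
static inline double tre_tauh(double v) {
  return 28.307 + 0.33 / (std::exp((v + 48.0) / 4.0) + std::exp(-(v + 407.0) / 50.0));
}

// TC calcium-regulated h-current voltage kinetics
static inline double tch_hinf(double v) { return 1.0 / (1.0 + std::exp((v + 75.0) / 5.5)); }
static inline double tch_taus(double v) {
  return 20.0 + 1000.0 / (std::exp((v + 71.5) / 14.2) + std::exp(-(v + 89.0) / 11.6));
}

struct Syn {
  int pre, post, kind;        // kind: 0 AMPA, 1 GABA_A, 2 GABA_B
  double gmax, erev, bind, unbind, pulse_dur, delay;
  double r, g, pulse_until;
  std::deque<double> events;  // delayed pulse-onset times
};

// [[Rcpp::export(name = ".run_engine")]]
List run_engine(List cfg) {
  const int n_htc = as<int>(cfg["n_htc"]);
  const int n_tc  = as<int>(cfg["n_tc"]);
  const int n_re  = as<int>(cfg["n_re"]);
  const int n     = n_htc + n_tc + n_re;
  const double dt = as<double>(cfg["dt"]);
  const long n_steps = (long)as<double>(cfg["n_steps"]);
  const int rec_every = as<int>(cfg["rec_every"]);

  List hp = cfg["htc"], tp = cfg["tc"], rp = cfg["re"], cp = cfg["ca"], np = cfg["noise"];

  // HTC parameters
  const double h_gna = hp["g_na"], h_gk = hp["g_k"], h_gtlt = hp["g_tlt"],
    h_gtht = hp["g_tht"], h_gl = hp["g_l"], h_el = hp["e_l"], h_gkl = hp["g_kl"],
    h_ekl = hp["e_kl"], h_gh = hp["g_h"], h_eh = hp["e_h"], h_gahp = hp["g_ahp"],
    h_ena = hp["e_na"], h_ek = hp["e_k"], h_cm = hp["c_m"], h_iapp = hp["i_app"];
  // TC parameters
  const double t_gna = tp["g_na"], t_gk = tp["g_k"], t_gtlt = tp["g_tlt"],
    t_gl = tp["g_l"], t_el = tp["e_l"], t_gkl = tp["g_kl"], t_ekl = tp["e_kl"],
    t_gh = tp["g_h"], t_eh = tp["e_h"], t_a = tp["a"], t_ena = tp["e_na"],
    t_ek = tp["e_k"], t_cm = tp["c_m"];
  // TC h-current printed rate constants (config-exposed)
  const double t_k_o1 = tp["k_o1"], t_k_o2 = tp["k_o2"], t_k_o3 = tp["k_o3"],
    t_k_p1 = tp["k_p1"], t_k_p2 = tp["k_p2"], t_ca_ref = tp["ca_ref"];
  // RE parameters
  const double r_gna = rp["g_na"], r_gk = rp["g_k"], r_gtre = rp["g_tre"],
    r_gl = rp["g_l"], r_el = rp["e_l"], r_gkl = rp["g_kl"], r_ekl = rp["e_kl"],
    r_ena = rp["e_na"], r_ek = rp["e_k"], r_cm = rp["c_m"];
  // calcium handling
  const double ca_o = cp["ca_o"], ca_rest = cp["ca_rest"],
    tau_htc = cp["tau_htc"], tau_tc = cp["tau_tc"], tau_re = cp["tau_re"];
  // noise
  const bool white_on = as<bool>(np["white_on"]);
  const bool poisson_on = as<bool>(np["poisson_on"]);
  const double sigma = std::sqrt(as<double>(np["variance"]));
  const bool em_standard = as<bool>(np["em_standard"]);
  const double mean_isi = np["mean_isi"];
  const double gs_tc_e = np["gs_tc_epsp"], gs_re_e = np["gs_re_epsp"],
    gs_re_i = np["gs_re_ipsp"], e_epsp = np["e_epsp"], e_ipsp = np["e_ipsp"];

  const bool record_currents = as<bool>(cfg["record_currents"]);
  const double v0 = as<double>(cfg["v0"]);

  // ---- state ----
  std::vector<double> V(n, v0), Vnew(n), Ca(n, ca_rest);
  std::vector<double> gn(n), gm(n), gh(n);          // Na/K gates
  std::vector<double> hT(n, 0.0);                   // T-current inactivation (TLT or TRE)
  std::vector<double> mT(n, 0.0);                   // RE T activation (integrated)
  std::vector<double> hTHT(n_htc, 0.0), rH(n_htc, 0.0), mAHP(n_htc, 0.0);
  std::vector<double> oH(n_tc, 0.0), pH(n_tc, 0.0), cH(n_tc, 0.0);
  std::vector<double> last_spike(n, -1e30), Vprev_full(n, v0);

  // steady-state initialisation at v0
  for (int i = 0; i < n; ++i) {
    const int type = i < n_htc ? 0 : (i < n_htc + n_tc ? 1 : 2);
    const double vshift = type == 2 ? 55.0 : 25.0;
    NaKRates rr = nak_rates(v0 + vshift);
    gn[i] = rr.an / (rr.an + rr.bn);
    gm[i] = rr.am / (rr.am + rr.bm);
    gh[i] = rr.ah / (rr.ah + rr.bh);
    if (type == 2) { mT[i] = tre_minf(v0); hT[i] = tre_hinf(v0); }
    else hT[i] = tlt_hinf(v0 + 2.0);
  }
  for (int i = 0; i < n_htc; ++i) {
    hTHT[i] = tht_hinf(v0);
    rH[i] = hr_inf(v0);
    double ca2 = 48.0 * ca_rest * ca_rest;
    mAHP[i] = ca2 / (ca2 + 0.09);
  }
  // TC h-current fractions start at the (clamped) fixed point of the printed rates
  // which is o = p = c = 0 at resting calcium.

  // ---- synapses ----
  IntegerVector s_pre = cfg["syn_pre"], s_post = cfg["syn_post"], s_kind = cfg["syn_kind"];
  NumericVector s_g = cfg["syn_g"], s_e = cfg["syn_e"], s_bind = cfg["syn_bind"],
    s_unbind = cfg["syn_unbind"], s_pdur = cfg["syn_pulse"], s_delay = cfg["syn_delay"];
  const int n_syn = s_pre.size();
  std::vector<Syn> syn(n_syn);
  for (int k = 0; k < n_syn; ++k) {
    syn[k].pre = s_pre[k]; syn[k].post = s_post[k]; syn[k].kind = s_kind[k];
    syn[k].gmax = s_g[k]; syn[k].erev = s_e[k]; syn[k].bind = s_bind[k];
    syn[k].unbind = s_unbind[k]; syn[k].pulse_dur = s_pdur[k]; syn[k].delay = s_delay[k];
    syn[k].r = 0.0; syn[k].g = 0.0; syn[k].pulse_until = -1.0;
  }
  // outgoing synapse index per cell
  std::vector< std::vector<int> > outgoing(n);
  for (int k = 0; k < n_syn; ++k) outgoing[syn[k].pre].push_back(k);

  IntegerVector gj_a = cfg["gj_a"], gj_b = cfg["gj_b"];
  NumericVector gj_g = cfg["gj_g"];
  const int n_gj = gj_a.size();

  // Poisson shot-noise trains: one EPSP train per TC, EPSP+IPSP per RE.
  // Each train keeps the most recent impulse time and the next scheduled one.
  const int n_train = poisson_on ? (n_tc + 2 * n_re) : 0;
  std::vector<double> tr_last(n_train, -1e30), tr_next(n_train, 0.0);
  for (int k = 0; k < n_train; ++k) tr_next[k] = exp_rand() * mean_isi;

  // ---- recording ----
  const long n_rec = n_steps / rec_every + 1;
  NumericMatrix Vrec(n_rec, n);
  NumericMatrix Irec = record_currents ? NumericMatrix(n_rec, 8) : NumericMatrix(1, 1);
  std::vector< std::vector<double> > spikes(n);
  long rec_i = 0;
  for (int i = 0; i < n; ++i) Vrec(0, i) = V[i];

  std::vector<double> Isyn(n, 0.0);

  for (long step = 0; step < n_steps; ++step) {
    const double t = step * dt;

    // synaptic transmitter windows + currents onto posts
    std::fill(Isyn.begin(), Isyn.end(), 0.0);
    for (int k = 0; k < n_syn; ++k) {
      Syn &s = syn[k];
      while (!s.events.empty() && s.events.front() <= t) {
        double until = s.events.front() + s.pulse_dur;
        if (until > s.pulse_until) s.pulse_until = until;
        s.events.pop_front();
      }
      double cur;
      if (s.kind == 2) {
        double g4 = s.g * s.g * s.g * s.g;
        cur = s.gmax * (g4 / (g4 + 100.0)) * (V[s.post] - s.erev);
      } else {
        cur = s.gmax * s.r * (V[s.post] - s.erev);
      }
      Isyn[s.post] += cur;
    }

    // cells
    double rec_IH = 0, rec_ITHT = 0, rec_ITLT = 0, rec_IAHP = 0, rec_IK = 0,
      rec_INa = 0, rec_mh2 = 0, rec_rH = 0;
    for (int i = 0; i < n; ++i) {
      const double v = V[i];
      double dv;
      if (i < n_htc) {                       // ---- HTC ----
        NaKRates rr = nak_rates(v + 25.0);
        double ik = h_gk * std::pow(gn[i], 4) * (v - h_ek);
        double ina = h_gna * gm[i] * gm[i] * gm[i] * gh[i] * (v - h_ena);
        double eca = RT2F_mV * std::log(ca_o / Ca[i]);
        double vtl = v + 2.0;
        double mtl = tlt_minf(vtl);
        double itlt = h_gtlt * mtl * mtl * hT[i] * (v - eca);
        double mht = tht_minf(v);
        double itht = h_gtht * mht * mht * hTHT[i] * (v - eca);
        double il = h_gl * (v - h_el) + h_gkl * (v - h_ekl);
        double ih = h_gh * rH[i] * (v - h_eh);
        double iahp = h_gahp * mAHP[i] * mAHP[i] * (v - h_ek);
        double igj = 0.0;
        for (int q = 0; q < n_gj; ++q) {
          if (gj_a[q] == i) igj += gj_g[q] * (v - V[gj_b[q]]);
          else if (gj_b[q] == i) igj += gj_g[q] * (v - V[gj_a[q]]);
        }
        dv = (-ina - ik - itlt - itht - il - ih - iahp - igj - Isyn[i] + h_iapp) / h_cm;

        if (record_currents && i == 0 && ((step + 1) % rec_every) == 0) {
          rec_IH = ih; rec_ITHT = itht; rec_ITLT = itlt; rec_IAHP = iahp;
          rec_IK = ik; rec_INa = ina; rec_mh2 = mht * mht * hTHT[i]; rec_rH = rH[i];
        }

        // gates
        gn[i] = clamp01(gn[i] + dt * (rr.an * (1 - gn[i]) - rr.bn * gn[i]));
        gm[i] = clamp01(gm[i] + dt * (rr.am * (1 - gm[i]) - rr.bm * gm[i]));
        gh[i] = clamp01(gh[i] + dt * (rr.ah * (1 - gh[i]) - rr.bh * gh[i]));
        hT[i] = clamp01(hT[i] + dt * (tlt_hinf(vtl) - hT[i]) / tlt_tauh(vtl));
        hTHT[i] = clamp01(hTHT[i] + dt * (tht_hinf(v) - hTHT[i]) / tht_tauh(v));
        rH[i] = clamp01(rH[i] + dt * (hr_inf(v) - rH[i]) / hr_tau(v));
        double ca2 = 48.0 * Ca[i] * Ca[i];
        mAHP[i] = clamp01(mAHP[i] + dt * (ca2 / (ca2 + 0.09) - mAHP[i]) * (ca2 + 0.09));
        double influx = -10.0 * (itlt + itht) / (2.0 * F_CA_ODE);
        if (influx < 0) influx = 0;
        Ca[i] += dt * (influx + (ca_rest - Ca[i]) / tau_htc);
        if (Ca[i] < 1e-10) Ca[i] = 1e-10;

        double vn = v + dt * dv;
        if (white_on) {
          double xi = norm_rand() * sigma;
          vn += em_standard ? std::sqrt(dt) * xi : dt * xi;
        }
        Vnew[i] = vn;
      } else if (i < n_htc + n_tc) {         // ---- TC ----
        const int j = i - n_htc;
        NaKRates rr = nak_rates(v + 25.0);
        double ik = t_gk * std::pow(gn[i], 4) * (v - t_ek);
        double ina = t_gna * gm[i] * gm[i] * gm[i] * gh[i] * (v - t_ena);
        double eca = RT2F_mV * std::log(ca_o / Ca[i]);
        double vtl = v + 2.0;
        double mtl = tlt_minf(vtl);
        double itlt = t_gtlt * mtl * mtl * hT[i] * (v - eca);
        double il = t_gl * (v - t_el) + t_gkl * (v - t_ekl);
        double hfac = oH[j] + t_a * (1.0 - cH[j] - oH[j]);
        if (hfac < 0) hfac = 0;
        if (hfac > 1.0 + t_a) hfac = 1.0 + t_a;
        double ih = t_gh * hfac * (v - t_eh);
        double inz = 0.0;
        if (poisson_on) {
          int kk = j;  // TC EPSP train index
          while (t >= tr_next[kk]) { tr_last[kk] = tr_next[kk]; tr_next[kk] += exp_rand() * mean_isi; }
          if (tr_last[kk] > -1e29) inz += -gs_tc_e * std::exp(tr_last[kk] - t) * (v - e_epsp);
        }
        dv = (-ina - ik - itlt - il - ih - Isyn[i] + inz) / t_cm;

        gn[i] = clamp01(gn[i] + dt * (rr.an * (1 - gn[i]) - rr.bn * gn[i]));
        gm[i] = clamp01(gm[i] + dt * (rr.am * (1 - gm[i]) - rr.bm * gm[i]));
        gh[i] = clamp01(gh[i] + dt * (rr.ah * (1 - gh[i]) - rr.bh * gh[i]));
        hT[i] = clamp01(hT[i] + dt * (tlt_hinf(vtl) - hT[i]) / tlt_tauh(vtl));
        double hinf = tch_hinf(v), taus = tch_taus(v);
        double ac = hinf / taus, bc = (1.0 - hinf) / taus;
        double o = oH[j], p = pH[j], c = cH[j];
        oH[j] = clamp01(o + dt * (t_k_o1 * (1.0 - c - o) - t_k_o2 * ((1.0 - p) / t_k_o3)));
        double car = Ca[i] / t_ca_ref;
        pH[j] = clamp01(p + dt * (t_k_p1 * (1.0 - p) - t_k_p2 * car * car));
        cH[j] = clamp01(c + dt * (bc * o - ac * c));
        double influx = -10.0 * itlt / (2.0 * F_CA_ODE);
        if (influx < 0) influx = 0;
        Ca[i] += dt * (influx + (ca_rest - Ca[i]) / tau_tc);
        if (Ca[i] < 1e-10) Ca[i] = 1e-10;

        Vnew[i] = v + dt * dv;
      } else {                               // ---- RE ----
        NaKRates rr = nak_rates(v + 55.0);
        double ik = r_gk * std::pow(gn[i], 4) * (v - r_ek);
        double ina = r_gna * gm[i] * gm[i] * gm[i] * gh[i] * (v - r_ena);
        double eca = RT2F_mV * std::log(ca_o / Ca[i]);
        double itre = r_gtre * mT[i] * mT[i] * hT[i] * (v - eca);
        double il = r_gl * (v - r_el) + r_gkl * (v - r_ekl);
        double inz = 0.0;
        if (poisson_on) {
          int ke = n_tc + 2 * (i - n_htc - n_tc);      // EPSP train
          int ki = ke + 1;                              // IPSP train
          while (t >= tr_next[ke]) { tr_last[ke] = tr_next[ke]; tr_next[ke] += exp_rand() * mean_isi; }
          while (t >= tr_next[ki]) { tr_last[ki] = tr_next[ki]; tr_next[ki] += exp_rand() * mean_isi; }
          if (tr_last[ke] > -1e29) inz += -gs_re_e * std::exp(tr_last[ke] - t) * (v - e_epsp);
          if (tr_last[ki] > -1e29) inz += -gs_re_i * std::exp(tr_last[ki] - t) * (v - e_ipsp);
        }
        dv = (-ina - ik - itre - il - Isyn[i] + inz) / r_cm;

        gn[i] = clamp01(gn[i] + dt * (rr.an * (1 - gn[i]) - rr.bn * gn[i]));
        gm[i] = clamp01(gm[i] + dt * (rr.am * (1 - gm[i]) - rr.bm * gm[i]));
        gh[i] = clamp01(gh[i] + dt * (rr.ah * (1 - gh[i]) - rr.bh * gh[i]));
        mT[i] = clamp01(mT[i] + dt * (tre_minf(v) - mT[i]) / tre_taum(v));
        hT[i] = clamp01(hT[i] + dt * (tre_hinf(v) - hT[i]) / tre_tauh(v));
        double influx = -10.0 * itre / (2.0 * F_CA_ODE);
        if (influx < 0) influx = 0;
        Ca[i] += dt * (influx + (ca_rest - Ca[i]) / tau_re);
        if (Ca[i] < 1e-10) Ca[i] = 1e-10;

        Vnew[i] = v + dt * dv;
      }
      if (!R_finite(Vnew[i]))
        stop("numerical blow-up in cell %d at t = %.3f ms", i + 1, t);
    }

    // synapse receptor/G-protein update (transmitter windows as of time t)
    for (int k = 0; k < n_syn; ++k) {
      Syn &s = syn[k];
      double T = (t < s.pulse_until) ? 0.5 : 0.0;
      s.r = clamp01(s.r + dt * (s.bind * T * (1.0 - s.r) - s.unbind * s.r));
      if (s.kind == 2) {
        s.g += dt * (0.18 * s.r - 0.034 * s.g);
        if (s.g < 0) s.g = 0;
      }
    }

    const double t_next = (step + 1) * dt;
    // spike detection at full rate (upward 0-crossing, 2-ms refractory)
    for (int i = 0; i < n; ++i) {
      if (Vprev_full[i] < 0.0 && Vnew[i] >= 0.0 && (t_next - last_spike[i]) >= 2.0) {
        last_spike[i] = t_next;
        spikes[i].push_back(t_next);
        for (size_t q = 0; q < outgoing[i].size(); ++q) {
          Syn &s = syn[outgoing[i][q]];
          s.events.push_back(t_next + s.delay);
        }
      }
      Vprev_full[i] = Vnew[i];
      V[i] = Vnew[i];
    }

    if (((step + 1) % rec_every) == 0) {
      ++rec_i;
      for (int i = 0; i < n; ++i) Vrec(rec_i, i) = V[i];
      if (record_currents) {
        Irec(rec_i, 0) = rec_IH; Irec(rec_i, 1) = rec_ITHT; Irec(rec_i, 2) = rec_ITLT;
        Irec(rec_i, 3) = rec_IAHP; Irec(rec_i, 4) = rec_IK; Irec(rec_i, 5) = rec_INa;
        Irec(rec_i, 6) = rec_mh2; Irec(rec_i, 7) = rec_rH;
      }
    }
    if ((step % 200000) == 0) Rcpp::checkUserInterrupt();
  }

  List spk(n);
  for (int i = 0; i < n; ++i) spk[i] = wrap(spikes[i]);
  List out = List::create(
    _["v"] = Vrec,
    _["spikes"] = spk,
    _["time"] = NumericVector::create() // filled on the R side
  );
  if (record_currents) out["currents"] = Irec;
  return out;
}
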