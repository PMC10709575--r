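// Compartmental CA1 neuron engine: backward-Euler cable solve on a tree
// (Hines elimination), exponential-Euler gating, event-driven AMPA+NMDA
// synapses and STDP. Units: mV, ms, nA, uS, nF.
//
// Compartments must be ordered so that parent[i] < i (soma = 0, parent -1).
// Gating variables per compartment: m, h (Na), n (KDR), a, b (KA), q (Ih),
// u (KM) -- always updated everywhere; channels absent from a compartment
// simply have gbar 0 there.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <sstream>
using namespace Rcpp;

static const int NGATE = 7; // m h n a b q u

struct Lut {
  // lookup over V in [vmin, vmax], linear interpolation
  double vmin, vmax, step, inv_step;
  std::vector<double> y;
  void build(double vmin_, double vmax_, double step_,
             double (*f)(double, const double*), const double* par) {
    vmin = vmin_; vmax = vmax_; step = step_; inv_step = 1.0 / step_;
    int n = (int)std::floor((vmax - vmin) / step) + 2;
    y.resize(n);
    for (int i = 0; i < n; ++i) y[i] = f(vmin + i * step, par);
  }
  inline double operator()(double v) const {
    if (v < vmin) v = vmin;
    if (v > vmax) v = vmax;
    double u = (v - vmin) * inv_step;
    int i = (int)u;
    double fr = u - i;
    return y[i] + fr * (y[i + 1] - y[i]);
  }
};

static inline double sig(double v, double half, double slope) {
  return 1.0 / (1.0 + std::exp(-(v - half) / slope));
}

// parameterized inf/decay functions for LUT construction; par layout varies
static double f_inf(double v, const double* p) { return sig(v, p[0], p[1]); }
// Na h: voltage-dependent tau -> store exp(-dt/tau(V))
static double f_nah_decay(double v, const double* p) {
  // p: half, slope(tau), base, amp, dt
  double tau = p[2] + p[3] / (1.0 + std::exp((v - p[0]) / p[1]));
  return 1.0 - std::exp(-p[4] / tau);
}
static double f_mg(double v, const double* p) {
  // p: eta (1/mM), gamma (1/mV), mg (mM)
  return 1.0 / (1.0 + p[0] * p[2] * std::exp(-p[1] * v));
}

static double getpar(const NumericVector& kin, const char* name) {
  if (!kin.hasAttribute("names")) stop("kinetics vector must be named");
  CharacterVector nm = kin.names();
  for (int i = 0; i < kin.size(); ++i)
    if (std::string(nm[i]) == name) return kin[i];
  stop(std::string("missing kinetics parameter: ") + name);
  return NA_REAL;
}

// [[Rcpp::export]]
List engine_run(List neuron, List syn, NumericMatrix stim, List ctrl) {
  // ---- neuron arrays ----
  IntegerVector parent = neuron["parent"];       // 0-based, -1 for root
  NumericVector c_nF = neuron["c_nF"];
  NumericVector gl = neuron["g_leak_uS"];
  NumericVector el = neuron["e_leak"];
  NumericVector gax = neuron["g_axial_uS"];      // to parent; root entry unused
  NumericMatrix gbar = neuron["gbar_uS"];        // ncomp x 5: na kdr ka ih km
  IntegerVector ka_dist = neuron["ka_distal"];   // 0 proximal variant, 1 distal
  NumericVector kin = neuron["kinetics"];
  const int nc = parent.size();
  for (int i = 1; i < nc; ++i)
    if (parent[i] < 0 || parent[i] >= i) stop("compartments must be parent-ordered");

  // ---- control ----
  double dt = as<double>(ctrl["dt"]);
  double duration = as<double>(ctrl["duration_ms"]);
  IntegerVector probes = ctrl["probes"];         // 0-based comp indices
  int record_stride = as<int>(ctrl["record_stride"]);
  int soma_comp = as<int>(ctrl["soma_comp"]);
  double soma_thr = as<double>(ctrl["soma_threshold"]);
  double dend_thr = as<double>(ctrl["dend_threshold"]);
  if (dt <= 0) stop("dt must be positive");
  const long nstep = (long)std::llround(duration / dt);

  // ---- initial state ----
  std::vector<double> V(nc), gate(nc * NGATE);
  bool have_init = ctrl.containsElementNamed("v0") && !Rf_isNull(ctrl["v0"]);
  // gating parameter tables
  double p_m[2]  = { getpar(kin, "na_m_half"),  getpar(kin, "na_m_slope") };
  double p_h[2]  = { getpar(kin, "na_h_half"),  getpar(kin, "na_h_slope") };
  double p_n[2]  = { getpar(kin, "kdr_n_half"), getpar(kin, "kdr_n_slope") };
  double p_ap[2] = { getpar(kin, "ka_a_half"),  getpar(kin, "ka_a_slope") };
  double p_ad[2] = { getpar(kin, "ka_a_half") + getpar(kin, "ka_dist_shift"),
                     getpar(kin, "ka_a_slope") };
  double p_b[2]  = { getpar(kin, "ka_b_half"),  getpar(kin, "ka_b_slope") };
  double p_q[2]  = { getpar(kin, "ih_q_half"),  getpar(kin, "ih_q_slope") };
  double p_u[2]  = { getpar(kin, "km_u_half"),  getpar(kin, "km_u_slope") };
  double p_hd[5] = { getpar(kin, "na_h_tau_half"), getpar(kin, "na_h_tau_slope"),
                     getpar(kin, "na_h_tau_base"), getpar(kin, "na_h_tau_amp"), dt };
  double p_mg[3] = { getpar(kin, "mg_eta"), getpar(kin, "mg_gamma"),
                     getpar(kin, "mg_mM") };

  Lut L_minf, L_hinf, L_ninf, L_apinf, L_adinf, L_binf, L_qinf, L_uinf,
      L_hdec, L_mg;
  const double VMIN = -150, VMAX = 80, VSTEP = 0.05;
  L_minf.build(VMIN, VMAX, VSTEP, f_inf, p_m);
  L_hinf.build(VMIN, VMAX, VSTEP, f_inf, p_h);
  L_ninf.build(VMIN, VMAX, VSTEP, f_inf, p_n);
  L_apinf.build(VMIN, VMAX, VSTEP, f_inf, p_ap);
  L_adinf.build(VMIN, VMAX, VSTEP, f_inf, p_ad);
  L_binf.build(VMIN, VMAX, VSTEP, f_inf, p_b);
  L_qinf.build(VMIN, VMAX, VSTEP, f_inf, p_q);
  L_uinf.build(VMIN, VMAX, VSTEP, f_inf, p_u);
  L_hdec.build(VMIN, VMAX, VSTEP, f_nah_decay, p_hd);
  L_mg.build(VMIN, VMAX, VSTEP, f_mg, p_mg);

  // constant-tau decay coefficients (1 - exp(-dt/tau))
  double d_m = 1.0 - std::exp(-dt / getpar(kin, "na_m_tau"));
  double d_n = 1.0 - std::exp(-dt / getpar(kin, "kdr_n_tau"));
  double d_a = 1.0 - std::exp(-dt / getpar(kin, "ka_a_tau"));
  double d_b = 1.0 - std::exp(-dt / getpar(kin, "ka_b_tau"));
  double d_q = 1.0 - std::exp(-dt / getpar(kin, "ih_q_tau"));
  double d_u = 1.0 - std::exp(-dt / getpar(kin, "km_u_tau"));

  double e_na = getpar(kin, "e_na"), e_k = getpar(kin, "e_k"),
         e_h = getpar(kin, "e_h"), e_syn = getpar(kin, "e_syn");

  if (have_init) {
    NumericVector v0 = ctrl["v0"];
    NumericMatrix g0m = ctrl["gating0"];
    if (v0.size() != nc || g0m.nrow() != nc || g0m.ncol() != NGATE)
      stop("initial state has wrong dimensions");
    for (int i = 0; i < nc; ++i) {
      V[i] = v0[i];
      for (int g = 0; g < NGATE; ++g) gate[i * NGATE + g] = g0m(i, g);
    }
  } else {
    for (int i = 0; i < nc; ++i) {
      double v = -65.0;
      V[i] = v;
      double* g = &gate[i * NGATE];
      g[0] = L_minf(v); g[1] = L_hinf(v); g[2] = L_ninf(v);
      g[3] = ka_dist[i] ? L_adinf(v) : L_apinf(v);
      g[4] = L_binf(v); g[5] = L_qinf(v); g[6] = L_uinf(v);
    }
  }

  // ---- synapses ----
  IntegerVector s_comp = syn["comp"];            // 0-based
  NumericVector s_g0 = syn["g0"];
  NumericVector s_A = clone(as<NumericVector>(syn["A0"]));
  NumericVector s_gmax = syn["gmax"];
  double nmda_ratio = as<double>(syn["nmda_ratio"]);
  // receptor saturation: 0 = linear summation, 1 = increments vanish once the
  // NMDA state reaches the single-activation level (kinetic-scheme-like cap)
  double nmda_sat = syn.containsElementNamed("nmda_sat") ?
    as<double>(syn["nmda_sat"]) : 0.0;
  double ampa_sat = syn.containsElementNamed("ampa_sat") ?
    as<double>(syn["ampa_sat"]) : 0.0;
  NumericVector pre_t = syn["pre_times"];        // concatenated, sorted per syn
  IntegerVector pre_off = syn["pre_offsets"];    // length nsyn+1, 0-based
  bool stdp_on = as<bool>(syn["stdp_on"]);
  const int ns = s_comp.size();

  double ar = getpar(kin, "ampa_rise"), ad = getpar(kin, "ampa_decay");
  double nr = getpar(kin, "nmda_rise"), nd = getpar(kin, "nmda_decay");
  auto dexp_norm = [](double tr, double td) {
    double tp = (tr * td / (td - tr)) * std::log(td / tr);
    return 1.0 / (std::exp(-tp / td) - std::exp(-tp / tr));
  };
  double norm_a = dexp_norm(ar, ad), norm_n = dexp_norm(nr, nd);
  double dec_ar = std::exp(-dt / ar), dec_ad = std::exp(-dt / ad);
  double dec_nr = std::exp(-dt / nr), dec_nd = std::exp(-dt / nd);

  std::vector<double> xa_r(ns, 0.0), xa_d(ns, 0.0), xn_r(ns, 0.0), xn_d(ns, 0.0);
  std::vector<int> pre_idx(ns);
  for (int s = 0; s < ns; ++s) pre_idx[s] = pre_off[s];

  // STDP
  double stdp_M = getpar(kin, "stdp_M"), stdp_V = getpar(kin, "stdp_V"),
         stdp_tau = getpar(kin, "stdp_tau"), stdp_d = getpar(kin, "stdp_d"),
         stdp_p = getpar(kin, "stdp_p");
  const double NONE = -1e18;
  std::vector<double> last_pre(ns, NONE), last_post(ns, NONE);
  std::vector<double> wlog; // t, syn(1-based), A, type(1 pot, -1 dep)
  std::vector<std::vector<double>> dend_spk(ns);
  std::vector<bool> dend_above(ns, false);
  std::vector<double> soma_spk;
  bool soma_above = V[soma_comp] >= soma_thr;
  for (int s = 0; s < ns; ++s) dend_above[s] = V[s_comp[s]] >= dend_thr;

  // ---- stimuli (rows: comp0, onset, dur, amp) ----
  const int nstim = stim.nrow();

  // ---- recording ----
  const int np = probes.size();
  long nrec = (record_stride > 0) ? (nstep / record_stride + 1) : 0;
  NumericMatrix vrec(np > 0 ? nrec : 0, np);
  NumericVector trec(np > 0 ? nrec : 0);
  long irec = 0;
  if (np > 0) {
    trec[0] = 0.0;
    for (int p = 0; p < np; ++p) vrec(0, p) = V[probes[p]];
    irec = 1;
  }

  double gate_min = 1.0, gate_max = 0.0;
  for (int i = 0; i < nc * NGATE; ++i) {
    if (gate[i] < gate_min) gate_min = gate[i];
    if (gate[i] > gate_max) gate_max = gate[i];
  }

  std::vector<double> diag(nc), rhs(nc);
  std::vector<int> step_pre;   // synapses with pre events this step (may repeat)
  std::vector<double> step_pre_t;

  for (long step = 0; step < nstep; ++step) {
    double t_prev = step * dt;
    double t_now = t_prev + dt;

    // 1. gating update from V^n (exponential Euler)
    for (int i = 0; i < nc; ++i) {
      double v = V[i];
      double* g = &gate[i * NGATE];
      g[0] += d_m * (L_minf(v) - g[0]);
      g[1] += L_hdec(v) * (L_hinf(v) - g[1]);
      g[2] += d_n * (L_ninf(v) - g[2]);
      g[3] += d_a * ((ka_dist[i] ? L_adinf(v) : L_apinf(v)) - g[3]);
      g[4] += d_b * (L_binf(v) - g[4]);
      g[5] += d_q * (L_qinf(v) - g[5]);
      g[6] += d_u * (L_uinf(v) - g[6]);
    }

    // 2. synaptic conductance states: decay + deliver pre spikes in (t_prev, t_now]
    step_pre.clear(); step_pre_t.clear();
    for (int s = 0; s < ns; ++s) {
      xa_r[s] *= dec_ar; xa_d[s] *= dec_ad;
      xn_r[s] *= dec_nr; xn_d[s] *= dec_nd;
      int end = pre_off[s + 1];
      while (pre_idx[s] < end && pre_t[pre_idx[s]] <= t_now) {
        double gpk = s_g0[s] + s_A[s];
        double inc_a = gpk * norm_a;
        double fa = 1.0;
        if (ampa_sat > 0 && inc_a > 0) {
          double fill = xa_d[s] / inc_a;
          if (fill > 1.0) fill = 1.0;
          fa = 1.0 - ampa_sat * fill;
          if (fa < 0) fa = 0;
        }
        xa_r[s] += fa * inc_a; xa_d[s] += fa * inc_a;
        double inc_n = nmda_ratio * gpk * norm_n;
        double f = 1.0;
        if (nmda_sat > 0 && inc_n > 0) {
          double fill = xn_d[s] / inc_n;
          if (fill > 1.0) fill = 1.0;
          f = 1.0 - nmda_sat * fill;
          if (f < 0) f = 0;
        }
        xn_r[s] += f * inc_n; xn_d[s] += f * inc_n;
        step_pre.push_back(s);
        step_pre_t.push_back(pre_t[pre_idx[s]]);
        ++pre_idx[s];
      }
    }

    // 3. assemble linear system (backward Euler, channels linearized at new gating)
    for (int i = 0; i < nc; ++i) {
      double* g = &gate[i * NGATE];
      double gna = gbar(i, 0) * g[0] * g[0] * g[0] * g[1];
      double gkdr = gbar(i, 1) * g[2];
      double gka = gbar(i, 2) * g[3] * g[4];
      double gih = gbar(i, 3) * g[5];
      double gkm = gbar(i, 4) * g[6];
      double cd = c_nF[i] / dt;
      diag[i] = cd + gl[i] + gna + gkdr + gka + gih + gkm;
      rhs[i] = cd * V[i] + gl[i] * el[i] + gna * e_na + (gkdr + gka + gkm) * e_k +
               gih * e_h;
    }
    for (int s = 0; s < ns; ++s) {
      int i = s_comp[s];
      double ga = xa_d[s] - xa_r[s];
      double gn = (xn_d[s] - xn_r[s]) * L_mg(V[i]);
      diag[i] += ga + gn;
      rhs[i] += (ga + gn) * e_syn;
    }
    for (int k = 0; k < nstim; ++k) {
      if (t_now >= stim(k, 1) && t_now < stim(k, 1) + stim(k, 2))
        rhs[(int)stim(k, 0)] += stim(k, 3);
    }
    // axial terms
    for (int i = 1; i < nc; ++i) {
      diag[i] += gax[i];
      diag[parent[i]] += gax[i];
    }
    // Hines elimination (children have larger indices)
    for (int i = nc - 1; i >= 1; --i) {
      double f = gax[i] / diag[i];
      diag[parent[i]] -= f * gax[i];
      rhs[parent[i]] += f * rhs[i];
    }
    V[0] = rhs[0] / diag[0];
    for (int i = 1; i < nc; ++i) V[i] = (rhs[i] + gax[i] * V[parent[i]]) / diag[i];

    // divergence check
    for (int i = 0; i < nc; ++i) {
      if (!std::isfinite(V[i]) || V[i] > 200.0 || V[i] < -200.0) {
        std::ostringstream msg;
        msg << "numerical divergence in compartment " << i + 1 << " at t = "
            << t_now << " ms (V = " << V[i] << ")";
        stop(msg.str());
      }
    }

    // 4. spike detection (single-excursion rule)
    double vs = V[soma_comp];
    if (!soma_above && vs >= soma_thr) { soma_spk.push_back(t_now); soma_above = true; }
    else if (soma_above && vs < soma_thr) soma_above = false;

    // 5. STDP: pre events first (in delivery order), then post events
    if (stdp_on) {
      const double inv2V2 = 1.0 / (2.0 * stdp_V * stdp_V);
      const double gauss_norm = 1.0 / (stdp_V * std::sqrt(2.0 * M_PI));
      for (size_t k = 0; k < step_pre.size(); ++k) {
        int s = step_pre[k];
        double tp = step_pre_t[k];
        if (last_post[s] > NONE / 2) {
          double delta = last_post[s] - tp; // <= 0
          if (delta < 0) {
            double mult = 1.0 - stdp_d * gauss_norm *
                          std::exp(-(delta - stdp_M) * (delta - stdp_M) * inv2V2);
            s_A[s] *= mult;
            if (s_A[s] < 0) s_A[s] = 0;
            wlog.push_back(tp); wlog.push_back(s + 1);
            wlog.push_back(s_A[s]); wlog.push_back(-1);
          }
        }
        last_pre[s] = tp;
      }
      for (int s = 0; s < ns; ++s) {
        double vd = V[s_comp[s]];
        if (!dend_above[s] && vd >= dend_thr) {
          dend_above[s] = true;
          dend_spk[s].push_back(t_now);
          if (last_pre[s] > NONE / 2) {
            double delta = t_now - last_pre[s]; // > 0
            if (delta > 0) {
              double head = s_gmax[s] - s_g0[s];
              s_A[s] += (head - s_A[s]) * stdp_p * std::exp(-delta / stdp_tau);
              if (s_A[s] < 0) s_A[s] = 0;
              if (s_A[s] > head) s_A[s] = head;
              wlog.push_back(t_now); wlog.push_back(s + 1);
              wlog.push_back(s_A[s]); wlog.push_back(1);
            }
          }
          last_post[s] = t_now;
        } else if (dend_above[s] && vd < dend_thr) dend_above[s] = false;
      }
    } else {
      // still track dendritic spikes for diagnostics
      for (int s = 0; s < ns; ++s) {
        double vd = V[s_comp[s]];
        if (!dend_above[s] && vd >= dend_thr) {
          dend_above[s] = true;
          dend_spk[s].push_back(t_now);
        } else if (dend_above[s] && vd < dend_thr) dend_above[s] = false;
      }
    }

    // 6. record
    if (np > 0 && ((step + 1) % record_stride == 0) && irec < nrec) {
      trec[irec] = t_now;
      for (int p = 0; p < np; ++p) vrec(irec, p) = V[probes[p]];
      ++irec;
    }
    // gating bounds bookkeeping (cheap scan every 20 steps)
    if (step % 20 == 0) {
      for (int i = 0; i < nc * NGATE; ++i) {
        if (gate[i] < gate_min) gate_min = gate[i];
        if (gate[i] > gate_max) gate_max = gate[i];
      }
    }
  }

  // outputs
  NumericMatrix vout(irec, np);
  NumericVector tout(irec);
  for (long r = 0; r < irec; ++r) {
    tout[r] = trec[r];
    for (int p = 0; p < np; ++p) vout(r, p) = vrec(r, p);
  }
  List dspk(ns);
  for (int s = 0; s < ns; ++s) dspk[s] = wrap(dend_spk[s]);
  NumericMatrix wl(wlog.size() / 4, 4);
  for (size_t r = 0; r < wlog.size() / 4; ++r)
    for (int c = 0; c < 4; ++c) wl(r, c) = wlog[4 * r + c];
  colnames(wl) = CharacterVector::create("time_ms", "synapse", "A_uS", "event");

  NumericVector vfin(nc);
  NumericMatrix gfin(nc, NGATE);
  for (int i = 0; i < nc; ++i) {
    vfin[i] = V[i];
    for (int g = 0; g < NGATE; ++g) gfin(i, g) = gate[i * NGATE + g];
  }
  // final gating into bounds too
  for (int i = 0; i < nc * NGATE; ++i) {
    if (gate[i] < gate_min) gate_min = gate[i];
    if (gate[i] > gate_max) gate_max = gate[i];
  }

  return List::create(
    _["time_ms"] = tout, _["v"] = vout,
    _["soma_spikes"] = wrap(soma_spk),
    _["dend_spikes"] = dspk,
    _["A_final"] = s_A,
    _["weight_log"] = wl,
    _["v_final"] = vfin, _["gating_final"] = gfin,
    _["gating_min"] = gate_min, _["gating_max"] = gate_max);
}

// Stand-alone Mg-block factor, same LUT-free formula as the engine uses.
// [[Rcpp::export]]
NumericVector mg_block_cpp(NumericVector v, double mg, double eta, double gamma) {
  NumericVector out(v.size());
  for (int i = 0; i < v.size(); ++i)
    out[i] = 1.0 / (1.0 + eta * mg * std::exp(-gamma * v[i]));
  return out;
}
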