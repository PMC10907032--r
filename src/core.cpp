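// Simulation kernels: forward-Euler integration of the minimal ventricular
// ionic model in 0-D (single cell) and on isotropic monodomain grids
// (1-D cable as ny = 1, 2-D sheet), with per-beat measurements taken at
// full temporal resolution.
//
// Parameter vector layout (kept in step with .param_names in R/params.R):
//  0 g_na   1 g_cal  2 g_kr   3 g_ks   4 g_k1   5 g_to
//  6 e_na   7 e_ca   8 e_k
//  9 eh_mid 10 eh_shift 11 kh  12 tauh_scale
// 13 tau_w  14 ca_gain 15 ca_decay 16 ca_alpha
// 17 vm     18 km
// 19 vd     20 kd
// 21 vw     22 kw
// 23 vk1    24 kk1
// 25 vkr    26 kkr   27 vkr_r 28 kkr_r
// 29 vks    30 kks
// 31 vto    32 kto
// 33 th_floor 34 th_amp 35 th_mid 36 th_sig (right/depolarized width)
// 37 th_sig_l (left/hyperpolarized width) 38 th_up (overshoot shelf, ms)

#include <Rcpp.h>
#include <cmath>
#include <vector>
#ifdef __SSE__
#include <xmmintrin.h>
#endif
using namespace Rcpp;

static const int NPAR = 39;

struct Pars {
  double g_na, g_cal, g_kr, g_ks, g_k1, g_to;
  double e_na, e_ca, e_k;
  double eh_mid, eh_shift, kh, tauh_scale;
  double tau_w, ca_gain, ca_decay, ca_alpha;
  double vm, km, vd, kd, vw, kw;
  double vk1, kk1, vkr, kkr, vkr_r, kkr_r, vks, kks, vto, kto;
  double th_floor, th_amp, th_mid, th_sig, th_sig_l, th_up;
};

static Pars unpack(const NumericVector& p) {
  if (p.size() < NPAR) stop("parameter vector too short");
  Pars q;
  q.g_na = p[0]; q.g_cal = p[1]; q.g_kr = p[2]; q.g_ks = p[3];
  q.g_k1 = p[4]; q.g_to = p[5];
  q.e_na = p[6]; q.e_ca = p[7]; q.e_k = p[8];
  q.eh_mid = p[9]; q.eh_shift = p[10]; q.kh = p[11]; q.tauh_scale = p[12];
  q.tau_w = p[13]; q.ca_gain = p[14]; q.ca_decay = p[15]; q.ca_alpha = p[16];
  q.vm = p[17]; q.km = p[18]; q.vd = p[19]; q.kd = p[20];
  q.vw = p[21]; q.kw = p[22];
  q.vk1 = p[23]; q.kk1 = p[24]; q.vkr = p[25]; q.kkr = p[26];
  q.vkr_r = p[27]; q.kkr_r = p[28]; q.vks = p[29]; q.kks = p[30];
  q.vto = p[31]; q.kto = p[32];
  q.th_floor = p[33]; q.th_amp = p[34]; q.th_mid = p[35]; q.th_sig = p[36];
  q.th_sig_l = p[37]; q.th_up = p[38];
  return q;
}

static inline double sig(double v, double v0, double k) {
  return 1.0 / (1.0 + std::exp(-(v - v0) / k));
}

// voltage-dependent pieces (exact, used by the cell kernel and for tables)
static inline double m3_of(const Pars& q, double v) {
  double m = sig(v, q.vm, q.km); return m * m * m;
}
static inline double dinf_of(const Pars& q, double v) {
  double z = (v - q.vd) / q.kd; return std::exp(-z * z);
}
static inline double winf_of(const Pars& q, double v) {
  return sig(-v, -q.vw, q.kw); // decreasing sigmoid, midpoint vw
}
static inline double hinf_of(const Pars& q, double v) {
  // availability curve; eh_shift moves the midpoint (drug effect)
  return sig(-(v), -(q.eh_mid + q.eh_shift), q.kh);
}
static inline double tauh0_of(const Pars& q, double v) {
  // asymmetric bump: gaussian on the hyperpolarized side (diastolic
  // recovery), flat-topped quartic on the depolarized side so the foot of a
  // propagating upstroke keeps slow inactivation while the plateau value
  // still drops below 1 ms above -30 mV
  double e;
  if (v >= q.th_mid) {
    double z = (v - q.th_mid) / q.th_sig;
    double z2 = z * z;
    e = std::exp(-z2 * z2 * z2);
  } else {
    double z = (v - q.th_mid) / q.th_sig_l;
    e = std::exp(-z * z);
  }
  // overshoot shelf: the fast-closure constraint applies at the dome
  // (plateau) voltage; above ~+2 mV the transient spike keeps its charge
  double shelf = q.th_up / (1.0 + std::exp(-(v - 2.0) / 4.0));
  return q.th_floor + q.th_amp * e + shelf;
}
static inline double gk1_gate(const Pars& q, double v) {
  return sig(-v, -q.vk1, q.kk1);
}
static inline double gkr_gate(const Pars& q, double v) {
  return sig(v, q.vkr, q.kkr) * sig(-v, -q.vkr_r, q.kkr_r);
}
static inline double gks_gate(const Pars& q, double v) {
  return sig(v, q.vks, q.kks);
}
static inline double gto_gate(const Pars& q, double v) {
  return sig(v, q.vto, q.kto);
}

// [[Rcpp::export(name = ".cpp_currents")]]
NumericVector cpp_currents(NumericVector p, double v, double h, double w) {
  Pars q = unpack(p);
  double i_na  = q.g_na * m3_of(q, v) * h * (v - q.e_na);
  double i_cal = q.g_cal * dinf_of(q, v) * w * (v - q.e_ca);
  double i_kr  = q.g_kr * gkr_gate(q, v) * (v - q.e_k);
  double i_ks  = q.g_ks * gks_gate(q, v) * (v - q.e_k);
  double i_k1  = q.g_k1 * gk1_gate(q, v) * (v - q.e_k);
  double i_to  = q.g_to * gto_gate(q, v) * (v - q.e_k);
  return NumericVector::create(
    _["i_na"] = i_na, _["i_cal"] = i_cal, _["i_kr"] = i_kr,
    _["i_ks"] = i_ks, _["i_k1"] = i_k1, _["i_to"] = i_to,
    _["i_total"] = i_na + i_cal + i_kr + i_ks + i_k1 + i_to);
}

// [[Rcpp::export(name = ".cpp_gates")]]
NumericVector cpp_gates(NumericVector p, double v, double ca_d) {
  Pars q = unpack(p);
  return NumericVector::create(
    _["h_inf"] = hinf_of(q, v),
    _["w_inf"] = winf_of(q, v),
    _["tau_h"] = q.tauh_scale * (1.0 + q.ca_alpha * ca_d) * tauh0_of(q, v),
    _["tau_h0"] = tauh0_of(q, v),
    _["m_inf3"] = m3_of(q, v),
    _["d_inf"] = dinf_of(q, v));
}

// -------------------------------------------------------------------------
// Single cell
// -------------------------------------------------------------------------

// [[Rcpp::export(name = ".cpp_cell_run")]]
List cpp_cell_run(NumericVector p, NumericVector state0,
                  NumericVector stim_times, double stim_dur, double stim_amp,
                  double t_end, double dt, double record_dt) {
  Pars q = unpack(p);
#ifdef __SSE__
  unsigned int csr_old = _mm_getcsr();
  _mm_setcsr(csr_old | 0x8040);   // flush denormal current/gate tails
#endif
  double v = state0[0], h = state0[1], w = state0[2], ca = state0[3];
  double t0 = state0.size() > 4 ? state0[4] : 0.0;

  const int nstep = (int)std::llround(t_end / dt);
  const int nstim = stim_times.size();

  // beat bookkeeping (one "beat" per stimulus)
  NumericVector b_top(nstim, NA_REAL), b_dvdt(nstim, NA_REAL),
      b_tdvdt(nstim, NA_REAL), b_pina(nstim, 0.0), b_pical(nstim, 0.0),
      b_act(nstim, NA_REAL), b_rep(nstim, NA_REAL), b_apd(nstim, NA_REAL),
      b_di(nstim, NA_REAL),
      b_vpre(nstim, NA_REAL), b_hpre(nstim, NA_REAL), b_wpre(nstim, NA_REAL),
      b_capre(nstim, NA_REAL);

  int rec_every = record_dt > 0 ? std::max(1, (int)std::llround(record_dt / dt)) : 0;
  int nrec = rec_every > 0 ? nstep / rec_every + 2 : 0;
  NumericMatrix trace(nrec, 8); // t v i_na i_cal h w ca i_k
  int irec = 0;

  int cur_beat = -1;   // index of the most recent stimulus
  int next_stim = 0;
  double prev_rep = NA_REAL;
  bool err = false; double err_t = NA_REAL;

  for (int istep = 0; istep <= nstep; ++istep) {
    double tl = istep * dt;        // run-local time: stimulus schedule
    double t = t0 + tl;            // absolute time: reported event times

    // stimulus onset bookkeeping (stim_times are relative to run start)
    while (next_stim < nstim && tl >= stim_times[next_stim] - 1e-9) {
      cur_beat = next_stim;
      b_top[cur_beat] = v;
      b_vpre[cur_beat] = v; b_hpre[cur_beat] = h;
      b_wpre[cur_beat] = w; b_capre[cur_beat] = ca;
      ++next_stim;
    }
    double istim = 0.0;
    if (cur_beat >= 0) {
      double since = tl - stim_times[cur_beat];
      if (since >= 0 && since < stim_dur) istim = stim_amp;
    }

    double i_na  = q.g_na * m3_of(q, v) * h * (v - q.e_na);
    double i_cal = q.g_cal * dinf_of(q, v) * w * (v - q.e_ca);
    double i_k   = q.g_kr * gkr_gate(q, v) * (v - q.e_k)
                 + q.g_ks * gks_gate(q, v) * (v - q.e_k)
                 + q.g_k1 * gk1_gate(q, v) * (v - q.e_k)
                 + q.g_to * gto_gate(q, v) * (v - q.e_k);

    if (rec_every > 0 && istep % rec_every == 0 && irec < nrec) {
      trace(irec, 0) = t; trace(irec, 1) = v; trace(irec, 2) = i_na;
      trace(irec, 3) = i_cal; trace(irec, 4) = h; trace(irec, 5) = w;
      trace(irec, 6) = ca; trace(irec, 7) = i_k;
      ++irec;
    }

    if (cur_beat >= 0) {
      if (i_na < b_pina[cur_beat]) b_pina[cur_beat] = i_na;
      if (i_cal < b_pical[cur_beat]) b_pical[cur_beat] = i_cal;
    }

    // forward Euler update
    double i_total = i_na + i_cal + i_k;
    double v_new = v - dt * (i_total + istim);        // C_m = 1 uF/cm^2
    double tau_h = q.tauh_scale * (1.0 + q.ca_alpha * ca) * tauh0_of(q, v);
    double h_new = h + dt * (hinf_of(q, v) - h) / tau_h;
    double w_new = w + dt * (winf_of(q, v) - w) / q.tau_w;
    double ca_new = ca + dt * (q.ca_gain * std::fabs(i_cal) - q.ca_decay * ca);
    if (h_new < 0) h_new = 0; else if (h_new > 1) h_new = 1;
    if (w_new < 0) w_new = 0; else if (w_new > 1) w_new = 1;
    if (ca_new < 0) ca_new = 0;

    if (!std::isfinite(v_new) || std::fabs(v_new) > 200.0) {
      err = true; err_t = t; break;
    }

    // upstroke velocity from membrane currents only: equals dv/dt outside
    // the stimulus window and removes the stimulus artifact inside it
    if (cur_beat >= 0) {
      double dvdt = -i_total;
      if (NumericVector::is_na(b_dvdt[cur_beat]) || dvdt > b_dvdt[cur_beat]) {
        b_dvdt[cur_beat] = dvdt; b_tdvdt[cur_beat] = t;
      }
    }

    // threshold crossings (linear interpolation in time)
    if (cur_beat >= 0) {
      if (v < -30.0 && v_new >= -30.0 &&
          NumericVector::is_na(b_act[cur_beat])) {
        double tc = t + dt * (-30.0 - v) / (v_new - v);
        b_act[cur_beat] = tc;
        if (!NumericVector::is_na(prev_rep)) b_di[cur_beat] = tc - prev_rep;
      }
      if (v >= -75.0 && v_new < -75.0 && !NumericVector::is_na(b_act[cur_beat]) &&
          NumericVector::is_na(b_rep[cur_beat])) {
        double tc = t + dt * (v - (-75.0)) / (v - v_new);
        b_rep[cur_beat] = tc;
        b_apd[cur_beat] = tc - b_act[cur_beat];
        prev_rep = tc;
      }
    }

    v = v_new; h = h_new; w = w_new; ca = ca_new;
  }

#ifdef __SSE__
  _mm_setcsr(csr_old);
#endif
  DataFrame beats = DataFrame::create(
    _["stim_time"] = stim_times, _["top"] = b_top, _["dvdt_max"] = b_dvdt,
    _["t_dvdt"] = b_tdvdt, _["peak_i_na"] = b_pina, _["peak_i_cal"] = b_pical,
    _["t_act"] = b_act, _["t_rep"] = b_rep, _["apd"] = b_apd, _["di"] = b_di,
    _["v_pre"] = b_vpre, _["h_pre"] = b_hpre, _["w_pre"] = b_wpre,
    _["ca_pre"] = b_capre);

  NumericMatrix tr;
  if (rec_every > 0) {
    tr = trace(Range(0, std::max(0, irec - 1)), _);
    colnames(tr) = CharacterVector::create("t", "v", "i_na", "i_cal",
                                           "h", "w", "ca_d", "i_k");
  }

  return List::create(
    _["beats"] = beats,
    _["trace"] = tr,
    _["state"] = NumericVector::create(_["v"] = v, _["h"] = h, _["w"] = w,
                                       _["ca_d"] = ca, _["t"] = t0 + t_end),
    _["error"] = err, _["error_t"] = err_t);
}

// -------------------------------------------------------------------------
// Tissue (cable ny = 1, sheet ny > 1), isotropic monodomain, no-flux edges
// -------------------------------------------------------------------------

// Interleaved lookup tables (float): 8 voltage terms per bin held
// contiguously so a node-step touches two cache-line rows; h-infinity kept
// separate (it is indexed at v - eh_shift). Float state halves memory
// traffic; measurement outputs remain double.
struct Tables {
  std::vector<float> row;      // 8 per bin: na cal kr ks k1 to winf itauh0
  std::vector<float> hinf;
  float vmin, inv_dv;
  int n;
};

static Tables build_tables(const Pars& q) {
  Tables tb;
  tb.vmin = -130.0f; double vmax = 90.0, dv = 0.02;
  tb.inv_dv = (float)(1.0 / dv);
  tb.n = (int)((vmax - tb.vmin) / dv) + 2;
  tb.row.resize(8 * tb.n);
  tb.hinf.resize(tb.n);
  for (int i = 0; i < tb.n; ++i) {
    double v = tb.vmin + i * dv;
    float* r = &tb.row[8 * i];
    r[0] = (float)(m3_of(q, v) * (v - q.e_na));
    r[1] = (float)(dinf_of(q, v) * (v - q.e_ca));
    r[2] = (float)(gkr_gate(q, v) * (v - q.e_k));
    r[3] = (float)(gks_gate(q, v) * (v - q.e_k));
    r[4] = (float)(gk1_gate(q, v) * (v - q.e_k));
    r[5] = (float)(gto_gate(q, v) * (v - q.e_k));
    r[6] = (float)winf_of(q, v);
    r[7] = (float)(1.0 / tauh0_of(q, v));
    Pars q0 = q; q0.eh_shift = 0.0;   // base availability; shift via index
    tb.hinf[i] = (float)hinf_of(q0, v);
  }
  return tb;
}

// Node parameters are tent-decomposed: par_j(i) = base[j] + fx[i]*dh[j]
// + fy[i]*dv[j] with j over (g_na, g_cal, g_kr, g_ks, g_k1, g_to,
// eh_shift, tauh_scale). A uniform medium has dh = dv = 0.
// [[Rcpp::export(name = ".cpp_tissue_run")]]
List cpp_tissue_run(NumericVector p_shared,
                    NumericVector base8, NumericVector dh8, NumericVector dv8,
                    NumericVector fx_, NumericVector fy_,
                    int nx, int ny, double dx, double dt, double diffusion,
                    Nullable<NumericMatrix> state0_,
                    IntegerVector stim_nodes, NumericVector stim_times,
                    double stim_dur, double stim_amp,
                    double t_end, int rec_node, double rec_dt,
                    double frame_dt, double frame_t0, double frame_t1,
                    bool stop_when_quiet, double quiet_v, int stop_node,
                    int max_cross) {
  Pars q = unpack(p_shared);
#ifdef __SSE__
  // flush denormals: sub-normal gate/current tails otherwise stall the FPU
  unsigned int csr_old = _mm_getcsr();
  _mm_setcsr(csr_old | 0x8040);
#endif
  Tables tb = build_tables(q);
  const int N = nx * ny;
  if (base8.size() != 8 || dh8.size() != 8 || dv8.size() != 8)
    stop("base/delta parameter vectors must have length 8");
  if (fx_.size() != N || fy_.size() != N) stop("fx/fy must have nx*ny entries");

  std::vector<float> fx(N), fy(N);
  for (int i = 0; i < N; ++i) { fx[i] = (float)fx_[i]; fy[i] = (float)fy_[i]; }
  float B[8], DH[8], DV[8];
  bool any_h = false, any_v = false;
  for (int j = 0; j < 8; ++j) {
    B[j] = (float)base8[j]; DH[j] = (float)dh8[j]; DV[j] = (float)dv8[j];
    if (DH[j] != 0) any_h = true;
    if (DV[j] != 0) any_v = true;
  }

  std::vector<float> v(N), h(N), w(N), ca(N), vnew(N);
  if (state0_.isNotNull()) {
    NumericMatrix s0(state0_);
    if (s0.ncol() != N || s0.nrow() != 4) stop("state0 must be 4 x nx*ny");
    for (int i = 0; i < N; ++i) {
      v[i] = (float)s0(0, i); h[i] = (float)s0(1, i);
      w[i] = (float)s0(2, i); ca[i] = (float)s0(3, i);
    }
  } else {
    for (int i = 0; i < N; ++i) {
      float eh = B[6] + fx[i] * DH[6] + fy[i] * DV[6];
      float vv = (float)q.e_k;
      float pos = (vv - eh - tb.vmin) * tb.inv_dv;
      int i0 = (int)pos;
      float fr = pos - i0;
      v[i] = vv;
      h[i] = tb.hinf[i0] + fr * (tb.hinf[i0 + 1] - tb.hinf[i0]);
      int j0 = (int)((vv - tb.vmin) * tb.inv_dv);
      w[i] = tb.row[8 * j0 + 6];
      ca[i] = 0.0f;
    }
  }

  std::vector<char> stim_mask(N, 0);
  for (int k = 0; k < stim_nodes.size(); ++k) {
    int idx = stim_nodes[k];
    if (idx < 0 || idx >= N) stop("stimulus node out of range");
    stim_mask[idx] = 1;
  }

  const int nstep = (int)std::llround(t_end / dt);
  const int nstim = stim_times.size();
  const float alpha = (float)(diffusion * dt / (dx * dx));
  const float fdt = (float)dt;

  NumericMatrix up(max_cross, N), down(max_cross, N);
  std::fill(up.begin(), up.end(), NA_REAL);
  std::fill(down.begin(), down.end(), NA_REAL);
  IntegerVector nup(N, 0), ndown(N, 0);

  int nframes = 0;
  if (frame_dt > 0 && frame_t1 > frame_t0)
    nframes = (int)((frame_t1 - frame_t0) / frame_dt) + 1;
  NumericMatrix frames(nframes > 0 ? nframes : 1, nframes > 0 ? N : 1);
  NumericVector frame_times(nframes > 0 ? nframes : 0);
  int iframe = 0;

  NumericVector b_top(nstim, NA_REAL), b_dvdt(nstim, NA_REAL),
      b_pina(nstim, 0.0), b_pical(nstim, 0.0);

  int rec_every = (rec_dt > 0 && rec_node >= 0)
      ? std::max(1, (int)std::llround(rec_dt / dt)) : 0;
  int nrec = rec_every > 0 ? nstep / rec_every + 2 : 0;
  NumericMatrix rtrace(nrec > 0 ? nrec : 1, 3);
  int irec = 0;

  int cur_beat = -1, next_stim = 0;
  bool err = false; double err_t = NA_REAL, t_stop = NA_REAL;
  double last_stim_end = nstim > 0 ? stim_times[nstim - 1] + stim_dur : -1e30;
  int quiet_check_every = std::max(1, (int)std::llround(1.0 / dt));

  const float* ROW = tb.row.data();
  const float* T_hinf = tb.hinf.data();
  const int ntb = tb.n;
  const float vmin = tb.vmin, inv_dv = tb.inv_dv;
  const float cainc = (float)q.ca_gain, cadec = (float)q.ca_decay,
      caal = (float)q.ca_alpha;
  const float itw = (float)(1.0 / q.tau_w);
  const float fstim_amp = (float)stim_amp;

  for (int istep = 0; istep <= nstep; ++istep) {
    double t = istep * dt;
    while (next_stim < nstim && t >= stim_times[next_stim] - 1e-9) {
      cur_beat = next_stim; ++next_stim;
      if (rec_node >= 0) b_top[cur_beat] = v[rec_node];
    }
    bool stim_on = false;
    if (cur_beat >= 0) {
      double since = t - stim_times[cur_beat];
      stim_on = (since >= 0 && since < stim_dur);
    }

    if (nframes > 0 && iframe < nframes &&
        t >= frame_t0 + iframe * frame_dt - 1e-9 && t <= frame_t1 + 1e-9) {
      for (int i = 0; i < N; ++i) frames(iframe, i) = v[i];
      frame_times[iframe] = t;
      ++iframe;
    }

    double rec_vold = rec_node >= 0 ? v[rec_node] : 0.0;
    if (rec_every > 0 && istep % rec_every == 0 && irec < nrec) {
      int i0r = (int)((v[rec_node] - vmin) * inv_dv);
      if (i0r < 0) i0r = 0; else if (i0r >= ntb) i0r = ntb - 1;
      float gna_r = B[0] + fx[rec_node] * DH[0] + fy[rec_node] * DV[0];
      rtrace(irec, 0) = t; rtrace(irec, 1) = v[rec_node];
      rtrace(irec, 2) = gna_r * ROW[8 * i0r] * h[rec_node];
      ++irec;
    }

    for (int iy = 0; iy < ny; ++iy) {
      for (int ixx = 0; ixx < nx; ++ixx) {
        const int i = iy * nx + ixx;
        const float fxi = fx[i], fyi = fy[i];
        const float vi = v[i];

        float pos = (vi - vmin) * inv_dv;
        int i0 = (int)pos;
        if (i0 < 0) { i0 = 0; pos = 0; }
        else if (i0 >= ntb - 1) { i0 = ntb - 2; pos = (float)i0; }
        const float fr = pos - i0;
        const float* r0 = ROW + 8 * i0;
        const float* r1 = r0 + 8;

        const float g_na = B[0] + fxi * DH[0] + fyi * DV[0];
        const float g_cal = B[1] + fxi * DH[1] + fyi * DV[1];
        const float i_na = g_na * (r0[0] + fr * (r1[0] - r0[0])) * h[i];
        const float i_cal = g_cal * (r0[1] + fr * (r1[1] - r0[1])) * w[i];
        const float i_k =
            (B[2] + fxi * DH[2] + fyi * DV[2]) * (r0[2] + fr * (r1[2] - r0[2]))
          + (B[3] + fxi * DH[3] + fyi * DV[3]) * (r0[3] + fr * (r1[3] - r0[3]))
          + (B[4] + fxi * DH[4] + fyi * DV[4]) * (r0[4] + fr * (r1[4] - r0[4]))
          + (B[5] + fxi * DH[5] + fyi * DV[5]) * (r0[5] + fr * (r1[5] - r0[5]));

        if (i == rec_node && cur_beat >= 0) {
          if (i_na < b_pina[cur_beat]) b_pina[cur_beat] = i_na;
          if (i_cal < b_pical[cur_beat]) b_pical[cur_beat] = i_cal;
        }

        float vl = ixx > 0      ? v[i - 1]  : v[i + 1];
        float vr = ixx < nx - 1 ? v[i + 1]  : v[i - 1];
        float lap = vl + vr - 2.0f * vi;
        if (ny > 1) {
          float vdn = iy > 0       ? v[i - nx] : v[i + nx];
          float vupp = iy < ny - 1 ? v[i + nx] : v[i - nx];
          lap += vdn + vupp - 2.0f * vi;
        }

        float istim = (stim_on && stim_mask[i]) ? fstim_amp : 0.0f;
        float vn = vi - fdt * (i_na + i_cal + i_k + istim) + alpha * lap;
        vnew[i] = vn;

        // gates (h-infinity indexed at v - eh_shift)
        const float eh = B[6] + fxi * DH[6] + fyi * DV[6];
        float hpos = pos - eh * inv_dv;
        int h0i = (int)hpos;
        float hfr;
        if (h0i < 0) { h0i = 0; hfr = 0; }
        else if (h0i >= ntb - 1) { h0i = ntb - 2; hfr = 1; }
        else hfr = hpos - h0i;
        const float hinf = T_hinf[h0i] + hfr * (T_hinf[h0i + 1] - T_hinf[h0i]);
        const float itau0 = r0[7] + fr * (r1[7] - r0[7]);
        const float ts = B[7] + fxi * DH[7] + fyi * DV[7];
        float hn = h[i] + fdt * (hinf - h[i]) * itau0 /
                   (ts * (1.0f + caal * ca[i]));
        if (hn < 0) hn = 0; else if (hn > 1) hn = 1;
        h[i] = hn;
        const float winf = r0[6] + fr * (r1[6] - r0[6]);
        float wn = w[i] + fdt * (winf - w[i]) * itw;
        if (wn < 0) wn = 0; else if (wn > 1) wn = 1;
        w[i] = wn;
        float can = ca[i] + fdt * (cainc * std::fabs(i_cal) - cadec * ca[i]);
        ca[i] = can > 0 ? can : 0;

        if (vi < -30.0f && vn >= -30.0f) {
          int k = nup[i];
          if (k < max_cross) up(k, i) = t + dt * (-30.0 - vi) / (vn - vi);
          nup[i] = k + 1;
        } else if (vi >= -75.0f && vn < -75.0f) {
          int k = ndown[i];
          if (k < max_cross) down(k, i) = t + dt * (vi + 75.0) / (vi - vn);
          ndown[i] = k + 1;
        }

        if (!(vn > -200.0f && vn < 200.0f)) { err = true; err_t = t; }
      }
    }
    if (err) break;
    std::swap(v, vnew);

    if (rec_node >= 0 && cur_beat >= 0) {
      double since = t - stim_times[cur_beat];
      if (since >= stim_dur) {
        double dvdt = (v[rec_node] - rec_vold) / dt;
        if (NumericVector::is_na(b_dvdt[cur_beat]) || dvdt > b_dvdt[cur_beat])
          b_dvdt[cur_beat] = dvdt;
      }
    }

    if (istep % quiet_check_every == 0 && t > last_stim_end + 5.0) {
      if (stop_when_quiet) {
        float vmaxx = -1e30f;
        for (int i = 0; i < N; ++i) if (v[i] > vmaxx) vmaxx = v[i];
        if (vmaxx < quiet_v) { t_stop = t; break; }
      }
      if (stop_node >= 0 && nup[stop_node] > 0) { t_stop = t; break; }
    }
  }

#ifdef __SSE__
  _mm_setcsr(csr_old);
#endif
  NumericMatrix state(4, N);
  for (int i = 0; i < N; ++i) {
    state(0, i) = v[i]; state(1, i) = h[i]; state(2, i) = w[i];
    state(3, i) = ca[i];
  }

  List out = List::create(
    _["up"] = up, _["down"] = down, _["n_up"] = nup, _["n_down"] = ndown,
    _["beats"] = DataFrame::create(_["stim_time"] = stim_times,
                                   _["top"] = b_top, _["dvdt_max"] = b_dvdt,
                                   _["peak_i_na"] = b_pina,
                                   _["peak_i_cal"] = b_pical),
    _["state"] = state, _["error"] = err, _["error_t"] = err_t,
    _["t_stop"] = t_stop);
  if (nframes > 0) {
    out["frames"] = frames(Range(0, std::max(0, iframe - 1)), _);
    out["frame_times"] = frame_times[Range(0, std::max(0, iframe - 1))];
  } else {
    out["frames"] = R_NilValue;
    out["frame_times"] = R_NilValue;
  }
  if (rec_every > 0 && irec > 0) {
    NumericMatrix rt = rtrace(Range(0, irec - 1), _);
    colnames(rt) = CharacterVector::create("t", "v", "i_na");
    out["rec_trace"] = rt;
  } else {
    out["rec_trace"] = R_NilValue;
  }
  return out;
}
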