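// Courtemanche-Ramirez-Nattel (1998) human atrial myocyte model.
//
// State layout (21 variables):
//   0 V      transmembrane potential (mV)
//   1 m, 2 h, 3 j          INa gates
//   4 oa, 5 oi             Ito gates
//   6 ua, 7 ui             IKur gates
//   8 xr                   IKr gate
//   9 xs                   IKs gate
//  10 d, 11 f, 12 fca      ICaL gates
//  13 u, 14 v, 15 w        SR release gates
//  16 Nai, 17 Ki, 18 Cai   intracellular concentrations (mM)
//  19 Caup, 20 Carel       SR concentrations (mM)
//
// Regional heterogeneity and chronic-AF remodeling enter as dimensionless
// multipliers on g_to, g_CaL, g_Kr, g_K1, g_Kur, g_Ks (in that order).
//
// All membrane currents are expressed in pA/pF; Cm = 100 pF is used to
// convert currents to ion fluxes in the concentration balances.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

static const int NSTATE = 21;

// physical constants
static const double Rgas = 8.3143;     // J/(mol K)
static const double Temp = 310.0;      // K
static const double Frdy = 96.4867;    // C/mmol
static const double Cm   = 100.0;      // pF

// cell geometry (um^3)
static const double Vi   = 13668.0;
static const double Vup  = 1109.52;
static const double Vrel = 96.48;

// extracellular concentrations (mM)
static const double Ko  = 5.4;
static const double Nao = 140.0;
static const double Cao = 1.8;

// maximal conductances / fluxes (baseline CRN)
static const double gNa   = 7.8;
static const double gK1   = 0.09;
static const double gto   = 0.1652;
static const double gKr   = 0.029411765;
static const double gKs   = 0.12941176;
static const double gCaL  = 0.12375;
static const double gbCa  = 0.001131;
static const double gbNa  = 0.0006744375;
static const double INaK_max  = 0.59933874;
static const double KmNai = 10.0;
static const double KmKo  = 1.5;
static const double INaCa_max = 1600.0;
static const double KmNa  = 87.5;
static const double KmCa  = 1.38;
static const double ksat  = 0.1;
static const double gam   = 0.35;
static const double IpCa_max  = 0.275;
static const double krel  = 30.0;
static const double tau_tr = 180.0;
static const double Iup_max = 0.005;
static const double Kup   = 0.00092;
static const double Caup_max = 15.0;

// buffers
static const double CMDN_max = 0.050;
static const double TRPN_max = 0.070;
static const double CSQN_max = 10.0;
static const double KmCmdn = 0.00238;
static const double KmTrpn = 0.0005;
static const double KmCsqn = 0.8;

static const double KQ10 = 3.0;

struct Scal {
  double to, cal, kr, k1, kur, ks;
};

static inline Scal make_scal(const NumericVector& s) {
  // order: g_to, g_CaL, g_Kr, g_K1, g_Kur, g_Ks
  Scal sc;
  sc.to = s[0]; sc.cal = s[1]; sc.kr = s[2];
  sc.k1 = s[3]; sc.kur = s[4]; sc.ks = s[5];
  return sc;
}

// guard against 0/0 in rate expressions of the form a*(V-c)/(1-exp(-k(V-c)))
static inline double safe_div(double num, double den, double lim) {
  return (std::fabs(den) < 1e-10) ? lim : num / den;
}

struct Gates {
  // steady states and time constants for the 13 voltage-dependent gates
  double minf, taum, hinf, tauh, jinf, tauj;
  double oainf, tauoa, oiinf, tauoi;
  double uainf, tauua, uiinf, tauui;
  double xrinf, tauxr, xsinf, tauxs;
  double dinf, taud, finf, tauf, winf, tauw;
};

static void gate_rates(double V, Gates& g) {
  // INa (Luo-Rudy formulations as adopted by CRN)
  double am = safe_div(0.32 * (V + 47.13), 1.0 - std::exp(-0.1 * (V + 47.13)), 3.2);
  double bm = 0.08 * std::exp(-V / 11.0);
  g.minf = am / (am + bm);
  g.taum = 1.0 / (am + bm);

  double ah, bh, aj, bj;
  if (V >= -40.0) {
    ah = 0.0;
    bh = 1.0 / (0.13 * (1.0 + std::exp(-(V + 10.66) / 11.1)));
    aj = 0.0;
    bj = 0.3 * std::exp(-2.535e-7 * V) / (1.0 + std::exp(-0.1 * (V + 32.0)));
  } else {
    ah = 0.135 * std::exp(-(V + 80.0) / 6.8);
    bh = 3.56 * std::exp(0.079 * V) + 3.1e5 * std::exp(0.35 * V);
    aj = (-1.2714e5 * std::exp(0.2444 * V) - 3.474e-5 * std::exp(-0.04391 * V)) *
         (V + 37.78) / (1.0 + std::exp(0.311 * (V + 79.23)));
    bj = 0.1212 * std::exp(-0.01052 * V) / (1.0 + std::exp(-0.1378 * (V + 40.14)));
  }
  g.hinf = ah / (ah + bh);
  g.tauh = 1.0 / (ah + bh);
  g.jinf = aj / (aj + bj);
  g.tauj = 1.0 / (aj + bj);

  // Ito
  double aoa = 0.65 / (std::exp(-(V + 10.0) / 8.5) + std::exp(-(V - 30.0) / 59.0));
  double boa = 0.65 / (2.5 + std::exp((V + 82.0) / 17.0));
  g.tauoa = 1.0 / ((aoa + boa) * KQ10);
  g.oainf = 1.0 / (1.0 + std::exp(-(V + 20.47) / 17.54));
  double aoi = 1.0 / (18.53 + std::exp((V + 113.7) / 10.95));
  double boi = 1.0 / (35.56 + std::exp(-(V + 1.26) / 7.44));
  g.tauoi = 1.0 / ((aoi + boi) * KQ10);
  g.oiinf = 1.0 / (1.0 + std::exp((V + 43.1) / 5.3));

  // IKur (activation rates shared with Ito activation)
  g.tauua = g.tauoa;
  g.uainf = 1.0 / (1.0 + std::exp(-(V + 30.3) / 9.6));
  double aui = 1.0 / (21.0 + std::exp(-(V - 185.0) / 28.0));
  double bui = std::exp((V - 158.0) / 16.0);
  g.tauui = 1.0 / ((aui + bui) * KQ10);
  g.uiinf = 1.0 / (1.0 + std::exp((V - 99.45) / 27.48));

  // IKr
  double axr = safe_div(0.0003 * (V + 14.1), 1.0 - std::exp(-(V + 14.1) / 5.0), 0.0015);
  double bxr = safe_div(7.3898e-5 * (V - 3.3328),
                        std::exp((V - 3.3328) / 5.1237) - 1.0, 3.7862e-4);
  g.tauxr = 1.0 / (axr + bxr);
  g.xrinf = 1.0 / (1.0 + std::exp(-(V + 14.1) / 6.5));

  // IKs
  double axs = safe_div(4e-5 * (V - 19.9), 1.0 - std::exp(-(V - 19.9) / 17.0), 6.8e-4);
  double bxs = safe_div(3.5e-5 * (V - 19.9), std::exp((V - 19.9) / 9.0) - 1.0, 3.15e-4);
  g.tauxs = 0.5 / (axs + bxs);
  g.xsinf = 1.0 / std::sqrt(1.0 + std::exp(-(V - 19.9) / 12.7));

  // ICaL
  double e1 = std::exp(-(V + 10.0) / 6.24);
  g.taud = safe_div((1.0 - e1), 0.035 * (V + 10.0) * (1.0 + e1), 1.0 / (0.035 * 6.24 * 2.0));
  g.dinf = 1.0 / (1.0 + std::exp(-(V + 10.0) / 8.0));
  double ef = std::exp(-(V + 28.0) / 6.9);
  g.finf = ef / (1.0 + ef);
  g.tauf = 9.0 / (0.0197 * std::exp(-0.0337 * 0.0337 * (V + 10.0) * (V + 10.0)) + 0.02);

  // w
  double e2 = std::exp(-(V - 7.9) / 5.0);
  g.tauw = safe_div(6.0 * (1.0 - e2), (1.0 + 0.3 * e2) * (V - 7.9), 6.0 / (5.0 * 1.3));
  g.winf = 1.0 - 1.0 / (1.0 + std::exp(-(V - 40.0) / 17.0));
}

struct Currents {
  double INa, IK1, Ito, IKur, IKr, IKs, ICaL, IpCa, INaK, INaCa, IbNa, IbCa;
  double Irel, Itr, Iup, Iupleak, Fn;
  double total;  // total transmembrane ionic current (pA/pF)
};

static void membrane_currents(const double* y, const Scal& sc, Currents& c) {
  const double V = y[0];
  const double Nai = y[16], Ki = y[17], Cai = y[18];
  const double Caup = y[19], Carel = y[20];
  const double RTF = Rgas * Temp / Frdy;

  double ENa = RTF * std::log(Nao / Nai);
  double EK  = RTF * std::log(Ko / Ki);
  double ECa = 0.5 * RTF * std::log(Cao / Cai);

  c.INa = gNa * y[1] * y[1] * y[1] * y[2] * y[3] * (V - ENa);
  c.IK1 = sc.k1 * gK1 * (V - EK) / (1.0 + std::exp(0.07 * (V + 80.0)));
  c.Ito = sc.to * gto * y[4] * y[4] * y[4] * y[5] * (V - EK);
  double gkur = 0.005 + 0.05 / (1.0 + std::exp(-(V - 15.0) / 13.0));
  c.IKur = sc.kur * gkur * y[6] * y[6] * y[6] * y[7] * (V - EK);
  c.IKr = sc.kr * gKr * y[8] * (V - EK) / (1.0 + std::exp((V + 15.0) / 22.4));
  c.IKs = sc.ks * gKs * y[9] * y[9] * (V - EK);
  c.ICaL = sc.cal * gCaL * y[10] * y[11] * y[12] * (V - 65.0);
  c.IpCa = IpCa_max * Cai / (0.0005 + Cai);

  double VFRT = V / RTF;
  double sigma = (std::exp(Nao / 67.3) - 1.0) / 7.0;
  double fNaK = 1.0 / (1.0 + 0.1245 * std::exp(-0.1 * VFRT) +
                       0.0365 * sigma * std::exp(-VFRT));
  c.INaK = INaK_max * fNaK * (1.0 / (1.0 + std::pow(KmNai / Nai, 1.5))) *
           (Ko / (Ko + KmKo));

  double eg  = std::exp(gam * VFRT);
  double eg1 = std::exp((gam - 1.0) * VFRT);
  c.INaCa = INaCa_max *
            (eg * Nai * Nai * Nai * Cao - eg1 * Nao * Nao * Nao * Cai) /
            ((KmNa * KmNa * KmNa + Nao * Nao * Nao) * (KmCa + Cao) *
             (1.0 + ksat * eg1));

  c.IbNa = gbNa * (V - ENa);
  c.IbCa = gbCa * (V - ECa);

  // SR fluxes (mM/ms)
  c.Irel = krel * y[13] * y[13] * y[14] * y[15] * (Carel - Cai);
  c.Itr = (Caup - Carel) / tau_tr;
  c.Iup = Iup_max / (1.0 + Kup / Cai);
  c.Iupleak = Iup_max * Caup / Caup_max;

  // Fn with currents in pA
  c.Fn = 1e-12 * Vrel * c.Irel -
         (5e-13 / Frdy) * (0.5 * c.ICaL * Cm - 0.2 * c.INaCa * Cm);

  c.total = c.INa + c.IK1 + c.Ito + c.IKur + c.IKr + c.IKs + c.ICaL +
            c.IpCa + c.INaK + c.INaCa + c.IbNa + c.IbCa;
}

static void conc_derivs(const double* y, const Currents& c, double* dy) {
  const double Cai = y[18], Caup = y[19], Carel = y[20];
  double f1 = Cm / (Frdy * Vi);
  dy[16] = (-3.0 * c.INaK - 3.0 * c.INaCa - c.IbNa - c.INa) * f1;
  dy[17] = (2.0 * c.INaK - c.IK1 - c.Ito - c.IKur - c.IKr - c.IKs) * f1;

  double B1 = (2.0 * c.INaCa - c.IpCa - c.ICaL - c.IbCa) * Cm / (2.0 * Frdy * Vi) +
              (Vup * (c.Iupleak - c.Iup) + c.Irel * Vrel) / Vi;
  double t1 = KmTrpn + Cai, t2 = KmCmdn + Cai;
  double B2 = 1.0 + TRPN_max * KmTrpn / (t1 * t1) + CMDN_max * KmCmdn / (t2 * t2);
  dy[18] = B1 / B2;

  dy[19] = c.Iup - c.Iupleak - c.Itr * Vrel / Vup;
  double q = KmCsqn + Carel;
  dy[20] = (c.Itr - c.Irel) / (1.0 + CSQN_max * KmCsqn / (q * q));
}

// Ca-handling gate targets (u, v depend on Fn; fca on Cai)
static inline void ca_gates(double Fn, double Cai,
                            double& uinf, double& vinf, double& tauv,
                            double& fcainf) {
  double e1 = std::exp(-(Fn - 3.4175e-13) / 13.67e-16);
  uinf = 1.0 / (1.0 + e1);
  vinf = 1.0 - 1.0 / (1.0 + std::exp(-(Fn - 6.835e-14) / 13.67e-16));
  tauv = 1.91 + 2.09 / (1.0 + e1);
  fcainf = 1.0 / (1.0 + Cai / 0.00035);
}
static const double tau_u = 8.0;
static const double tau_fca = 2.0;

// full right-hand side (pure derivative evaluation, used for tests and
// reference integrations)
static void crn_rhs(const double* y, const Scal& sc, double istim, double* dy) {
  Gates g;
  gate_rates(y[0], g);
  Currents c;
  membrane_currents(y, sc, c);

  dy[0] = -(c.total + istim);
  dy[1] = (g.minf - y[1]) / g.taum;
  dy[2] = (g.hinf - y[2]) / g.tauh;
  dy[3] = (g.jinf - y[3]) / g.tauj;
  dy[4] = (g.oainf - y[4]) / g.tauoa;
  dy[5] = (g.oiinf - y[5]) / g.tauoi;
  dy[6] = (g.uainf - y[6]) / g.tauua;
  dy[7] = (g.uiinf - y[7]) / g.tauui;
  dy[8] = (g.xrinf - y[8]) / g.tauxr;
  dy[9] = (g.xsinf - y[9]) / g.tauxs;
  dy[10] = (g.dinf - y[10]) / g.taud;
  dy[11] = (g.finf - y[11]) / g.tauf;
  double uinf, vinf, tauv, fcainf;
  ca_gates(c.Fn, y[18], uinf, vinf, tauv, fcainf);
  dy[12] = (fcainf - y[12]) / tau_fca;
  dy[13] = (uinf - y[13]) / tau_u;
  dy[14] = (vinf - y[14]) / tauv;
  dy[15] = (g.winf - y[15]) / g.tauw;
  conc_derivs(y, c, dy);
}

// one Rush-Larsen step in place; istim in pA/pF
static inline void rl_step(double* y, const Scal& sc, double istim, double dt) {
  Gates g;
  gate_rates(y[0], g);
  Currents c;
  membrane_currents(y, sc, c);

  double dy[NSTATE];
  conc_derivs(y, c, dy);

  // exponential (Rush-Larsen) update for all gates
  y[1] = g.minf + (y[1] - g.minf) * std::exp(-dt / g.taum);
  y[2] = g.hinf + (y[2] - g.hinf) * std::exp(-dt / g.tauh);
  y[3] = g.jinf + (y[3] - g.jinf) * std::exp(-dt / g.tauj);
  y[4] = g.oainf + (y[4] - g.oainf) * std::exp(-dt / g.tauoa);
  y[5] = g.oiinf + (y[5] - g.oiinf) * std::exp(-dt / g.tauoi);
  y[6] = g.uainf + (y[6] - g.uainf) * std::exp(-dt / g.tauua);
  y[7] = g.uiinf + (y[7] - g.uiinf) * std::exp(-dt / g.tauui);
  y[8] = g.xrinf + (y[8] - g.xrinf) * std::exp(-dt / g.tauxr);
  y[9] = g.xsinf + (y[9] - g.xsinf) * std::exp(-dt / g.tauxs);
  y[10] = g.dinf + (y[10] - g.dinf) * std::exp(-dt / g.taud);
  y[11] = g.finf + (y[11] - g.finf) * std::exp(-dt / g.tauf);
  double uinf, vinf, tauv, fcainf;
  ca_gates(c.Fn, y[18], uinf, vinf, tauv, fcainf);
  y[12] = fcainf + (y[12] - fcainf) * std::exp(-dt / tau_fca);
  y[13] = uinf + (y[13] - uinf) * std::exp(-dt / tau_u);
  y[14] = vinf + (y[14] - vinf) * std::exp(-dt / tauv);
  y[15] = g.winf + (y[15] - g.winf) * std::exp(-dt / g.tauw);

  // forward Euler for V and concentrations
  y[0] += dt * (-(c.total + istim));
  for (int k = 16; k < NSTATE; ++k) y[k] += dt * dy[k];
}

// [[Rcpp::export]]
NumericVector crn_initial_state_cpp() {
  NumericVector y(NSTATE);
  y[0] = -81.18;
  y[1] = 2.908e-3;  y[2] = 9.649e-1;  y[3] = 9.775e-1;
  y[4] = 3.043e-2;  y[5] = 9.992e-1;
  y[6] = 4.966e-3;  y[7] = 9.986e-1;
  y[8] = 3.296e-5;  y[9] = 1.869e-2;
  y[10] = 1.367e-4; y[11] = 9.996e-1; y[12] = 7.755e-1;
  y[13] = 0.0;      y[14] = 1.0;      y[15] = 9.992e-1;
  y[16] = 11.17;    y[17] = 139.0;    y[18] = 1.013e-4;
  y[19] = 1.488;    y[20] = 1.488;
  return y;
}

// [[Rcpp::export]]
NumericVector crn_rhs_cpp(NumericVector state, NumericVector scalars,
                          double istim) {
  if (state.size() != NSTATE) stop("state must have 21 elements");
  for (int i = 0; i < NSTATE; ++i)
    if (!R_finite(state[i])) stop("non-finite value in state");
  Scal sc = make_scal(scalars);
  NumericVector dy(NSTATE);
  crn_rhs(REAL(state), sc, istim, REAL(dy));
  return dy;
}

// Pace a single cell. Records Vm at `record_dt` ms cadence over the last
// `record_ms` milliseconds (record_ms <= 0 records the whole run).
// Returns list(times, vm, state).
// [[Rcpp::export]]
List crn_pace_cpp(NumericVector state0, NumericVector scalars,
                  double bcl, int n_beats, double stim_amp, double stim_dur,
                  double dt, double record_ms, double record_dt) {
  Scal sc = make_scal(scalars);
  double y[NSTATE];
  for (int i = 0; i < NSTATE; ++i) y[i] = state0[i];

  double total = bcl * n_beats;
  double t_rec0 = (record_ms > 0.0) ? std::max(0.0, total - record_ms) : 0.0;
  long nstep = (long)std::llround(total / dt);
  long nrec = (long)std::floor((total - t_rec0) / record_dt) + 1;
  NumericVector times(nrec), vm(nrec);
  long irec = 0;

  for (long s = 0; s <= nstep; ++s) {
    double t = s * dt;
    if (t >= t_rec0 - 1e-9 && irec < nrec) {
      double tnext = t_rec0 + irec * record_dt;
      if (t >= tnext - dt * 0.5) {
        times[irec] = t;
        vm[irec] = y[0];
        ++irec;
      }
    }
    if (s == nstep) break;
    double tb = t - bcl * std::floor(t / bcl);
    // stimulus applied as an inward (depolarizing) current
    double istim = (tb < stim_dur) ? -stim_amp : 0.0;
    rl_step(y, sc, istim, dt);
    if (std::fabs(y[0]) > 200.0)
      stop("numerical blow-up: |Vm| > 200 mV at t = %f ms", t);
  }
  if (irec < nrec) {
    times = head(times, irec);
    vm = head(vm, irec);
  }
  NumericVector yout(NSTATE);
  for (int i = 0; i < NSTATE; ++i) yout[i] = y[i];
  return List::create(_["times"] = times, _["vm"] = vm, _["state"] = yout);
}

// Record the full state trajectory over the final paced cycle at `sample_dt`
// cadence (used to build phase-distribution initial conditions for spiral
// waves). Returns a NSTATE x n_samples matrix.
// [[Rcpp::export]]
NumericMatrix crn_cycle_states_cpp(NumericVector state0, NumericVector scalars,
                                   double bcl, int n_beats, double stim_amp,
                                   double stim_dur, double dt,
                                   double sample_dt) {
  Scal sc = make_scal(scalars);
  double y[NSTATE];
  for (int i = 0; i < NSTATE; ++i) y[i] = state0[i];
  double total = bcl * n_beats;
  double t_rec0 = bcl * (n_beats - 1);
  long nstep = (long)std::llround(total / dt);
  int nsamp = (int)std::floor((total - t_rec0) / sample_dt);
  NumericMatrix out(NSTATE, nsamp);
  int isamp = 0;
  for (long s = 0; s <= nstep; ++s) {
    double t = s * dt;
    if (isamp < nsamp && t >= t_rec0 + isamp * sample_dt - dt * 0.5) {
      for (int i = 0; i < NSTATE; ++i) out(i, isamp) = y[i];
      ++isamp;
    }
    if (s == nstep) break;
    double tb = t - bcl * std::floor(t / bcl);
    double istim = (tb < stim_dur) ? -stim_amp : 0.0;
    rl_step(y, sc, istim, dt);
    if (std::fabs(y[0]) > 200.0)
      stop("numerical blow-up: |Vm| > 200 mV at t = %f ms", t);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Lookup tables for the tissue solver.
//
// Voltage-dependent gate targets are tabulated as (x_inf, exp(-dt/tau_x))
// pairs on a uniform V grid; current shape factors likewise. Tables are
// rebuilt whenever dt changes.

struct LUT {
  double vmin, vmax, dv, inv_dv, dt;
  int n;
  // 13 gates x 2 numbers
  std::vector<double> ginf[13], gexp[13];
  // current factors
  std::vector<double> ik1_f, gkur_f, ikr_f, fnak_f, enaca1, enaca2;
  double exp_fca, exp_u;
  bool ready = false;
} lut;

static void build_lut(double dt) {
  lut.vmin = -120.0; lut.vmax = 80.0; lut.dv = 0.02;
  lut.n = (int)std::lround((lut.vmax - lut.vmin) / lut.dv) + 1;
  lut.inv_dv = 1.0 / lut.dv;
  lut.dt = dt;
  for (int k = 0; k < 13; ++k) {
    lut.ginf[k].resize(lut.n);
    lut.gexp[k].resize(lut.n);
  }
  lut.ik1_f.resize(lut.n); lut.gkur_f.resize(lut.n); lut.ikr_f.resize(lut.n);
  lut.fnak_f.resize(lut.n); lut.enaca1.resize(lut.n); lut.enaca2.resize(lut.n);
  const double RTF = Rgas * Temp / Frdy;
  double sigma = (std::exp(Nao / 67.3) - 1.0) / 7.0;
  for (int i = 0; i < lut.n; ++i) {
    double V = lut.vmin + i * lut.dv;
    Gates g;
    gate_rates(V, g);
    const double inf[13] = {g.minf, g.hinf, g.jinf, g.oainf, g.oiinf,
                            g.uainf, g.uiinf, g.xrinf, g.xsinf, g.dinf,
                            g.finf, g.winf, 0.0};
    const double tau[13] = {g.taum, g.tauh, g.tauj, g.tauoa, g.tauoi,
                            g.tauua, g.tauui, g.tauxr, g.tauxs, g.taud,
                            g.tauf, g.tauw, 1.0};
    for (int k = 0; k < 12; ++k) {
      lut.ginf[k][i] = inf[k];
      lut.gexp[k][i] = std::exp(-dt / tau[k]);
    }
    double VFRT = V / RTF;
    lut.ik1_f[i] = 1.0 / (1.0 + std::exp(0.07 * (V + 80.0)));
    lut.gkur_f[i] = 0.005 + 0.05 / (1.0 + std::exp(-(V - 15.0) / 13.0));
    lut.ikr_f[i] = 1.0 / (1.0 + std::exp((V + 15.0) / 22.4));
    lut.fnak_f[i] = 1.0 / (1.0 + 0.1245 * std::exp(-0.1 * VFRT) +
                           0.0365 * sigma * std::exp(-VFRT));
    lut.enaca1[i] = std::exp(gam * VFRT);
    lut.enaca2[i] = std::exp((gam - 1.0) * VFRT);
  }
  lut.exp_fca = std::exp(-dt / tau_fca);
  lut.exp_u = std::exp(-dt / tau_u);
  lut.ready = true;
}

static inline void lut_pos(double V, int& i0, double& w) {
  double x = (V - lut.vmin) * lut.inv_dv;
  if (x < 0.0) x = 0.0;
  if (x > lut.n - 1.001) x = lut.n - 1.001;
  i0 = (int)x;
  w = x - i0;
}
static inline double lut_at(const std::vector<double>& t, int i0, double w) {
  return t[i0] + w * (t[i0 + 1] - t[i0]);
}

// One Rush-Larsen step using the lookup tables. Nernst potentials are
// supplied by the caller (they drift slowly with the concentrations and are
// refreshed every few steps by the tissue loop).
static inline void rl_step_lut(double* y, const Scal& sc, double istim,
                               double ENa, double EK, double ECa) {
  const double V = y[0];
  const double Nai = y[16], Cai = y[18];
  const double Caup = y[19], Carel = y[20];
  int i0; double w;
  lut_pos(V, i0, w);

  Currents c;
  c.INa = gNa * y[1] * y[1] * y[1] * y[2] * y[3] * (V - ENa);
  c.IK1 = sc.k1 * gK1 * (V - EK) * lut_at(lut.ik1_f, i0, w);
  c.Ito = sc.to * gto * y[4] * y[4] * y[4] * y[5] * (V - EK);
  c.IKur = sc.kur * lut_at(lut.gkur_f, i0, w) * y[6] * y[6] * y[6] * y[7] * (V - EK);
  c.IKr = sc.kr * gKr * y[8] * (V - EK) * lut_at(lut.ikr_f, i0, w);
  c.IKs = sc.ks * gKs * y[9] * y[9] * (V - EK);
  c.ICaL = sc.cal * gCaL * y[10] * y[11] * y[12] * (V - 65.0);
  c.IpCa = IpCa_max * Cai / (0.0005 + Cai);
  double kn = KmNai / Nai;
  c.INaK = INaK_max * lut_at(lut.fnak_f, i0, w) *
           (1.0 / (1.0 + kn * std::sqrt(kn))) * (Ko / (Ko + KmKo));
  double eg = lut_at(lut.enaca1, i0, w), eg1 = lut_at(lut.enaca2, i0, w);
  c.INaCa = INaCa_max *
            (eg * Nai * Nai * Nai * Cao - eg1 * Nao * Nao * Nao * Cai) /
            ((KmNa * KmNa * KmNa + Nao * Nao * Nao) * (KmCa + Cao) *
             (1.0 + ksat * eg1));
  c.IbNa = gbNa * (V - ENa);
  c.IbCa = gbCa * (V - ECa);
  c.Irel = krel * y[13] * y[13] * y[14] * y[15] * (Carel - Cai);
  c.Itr = (Caup - Carel) / tau_tr;
  c.Iup = Iup_max / (1.0 + Kup / Cai);
  c.Iupleak = Iup_max * Caup / Caup_max;
  c.Fn = 1e-12 * Vrel * c.Irel -
         (5e-13 / Frdy) * (0.5 * c.ICaL * Cm - 0.2 * c.INaCa * Cm);
  c.total = c.INa + c.IK1 + c.Ito + c.IKur + c.IKr + c.IKs + c.ICaL +
            c.IpCa + c.INaK + c.INaCa + c.IbNa + c.IbCa;

  double dy[NSTATE];
  conc_derivs(y, c, dy);

  // voltage gates: tables 0..10 update states y[1..11] (m..f); table 11 is w
  for (int k = 0; k < 11; ++k) {
    double xi = lut_at(lut.ginf[k], i0, w);
    double xe = lut_at(lut.gexp[k], i0, w);
    y[k + 1] = xi + (y[k + 1] - xi) * xe;
  }
  {
    double xi = lut_at(lut.ginf[11], i0, w);
    double xe = lut_at(lut.gexp[11], i0, w);
    y[15] = xi + (y[15] - xi) * xe;
  }
  double uinf, vinf, tauv, fcainf;
  ca_gates(c.Fn, Cai, uinf, vinf, tauv, fcainf);
  y[12] = fcainf + (y[12] - fcainf) * lut.exp_fca;
  y[13] = uinf + (y[13] - uinf) * lut.exp_u;
  y[14] = vinf + (y[14] - vinf) * std::exp(-lut.dt / tauv);

  y[0] += lut.dt * (-(c.total + istim));
  for (int k = 16; k < NSTATE; ++k) y[k] += lut.dt * dy[k];
}

// ---------------------------------------------------------------------------
// Monodomain tissue solver.
//
// Operator splitting (Godunov): one reaction step (Rush-Larsen, LUT) followed
// by one explicit diffusion step using a prebuilt sparse Laplacian-like
// operator L so that dV = dt * (L V) with no-flux boundaries encoded in L.
//
// states:   NSTATE x N matrix (column-major, one column per node)
// L:        CSR arrays (ptr 0-based length N+1, idx 0-based, val) with units
//           1/ms once multiplied by V in mV
// scal_idx: per-node 0-based row index into scal_mat (6 x nregion)
// stim:     matrix with columns (node0, onset, period, amplitude, duration,
//           count); period <= 0 means one-shot
//
// Records Vm every record_dt ms into a (N x nframes) matrix.
// [[Rcpp::export]]
List monodomain_run_cpp(NumericMatrix states, IntegerVector Lptr,
                        IntegerVector Lidx, NumericVector Lval,
                        IntegerVector scal_idx, NumericMatrix scal_mat,
                        NumericMatrix stim, double duration, double dt,
                        double record_dt, double t0) {
  const int N = states.ncol();
  if (states.nrow() != NSTATE) stop("states must have 21 rows");
  build_lut(dt);

  std::vector<Scal> scals(scal_mat.ncol());
  for (int r = 0; r < scal_mat.ncol(); ++r) {
    Scal s = {scal_mat(0, r), scal_mat(1, r), scal_mat(2, r),
              scal_mat(3, r), scal_mat(4, r), scal_mat(5, r)};
    scals[r] = s;
  }

  long nstep = (long)std::llround(duration / dt);
  int nframes = (int)std::floor(duration / record_dt) + 1;
  NumericMatrix frames(N, nframes);
  NumericVector ftimes(nframes);
  int irec = 0;

  std::vector<double> vold(N), dv(N);
  std::vector<double> istim(N, 0.0);
  std::vector<double> eNa(N), eK(N), eCa(N);
  double* Y = REAL(states);
  const double RTF = Rgas * Temp / Frdy;
  const int nernst_every = 10;  // refresh Nernst potentials every 10 steps

  for (long s = 0; s <= nstep; ++s) {
    double t = s * dt;
    double tnext = irec * record_dt;
    if (irec < nframes && t >= tnext - dt * 0.5) {
      for (int n = 0; n < N; ++n) frames(n, irec) = Y[(size_t)n * NSTATE];
      ftimes[irec] = t0 + t;
      ++irec;
    }
    if (s == nstep) break;

    if (s % nernst_every == 0) {
      for (int n = 0; n < N; ++n) {
        const double* y = Y + (size_t)n * NSTATE;
        eNa[n] = RTF * std::log(Nao / y[16]);
        eK[n] = RTF * std::log(Ko / y[17]);
        eCa[n] = 0.5 * RTF * std::log(Cao / y[18]);
      }
    }

    // stimulus currents this step (sparse: touch only active ranges)
    std::vector<std::pair<int, int> > active;
    for (int k = 0; k < stim.nrow(); ++k) {
      double rel = t - stim(k, 2);
      if (rel < 0) continue;
      double per = stim(k, 3);
      int count = (int)stim(k, 5);
      if (per > 0) {
        double cyc = std::floor(rel / per);
        if (cyc >= count) continue;
        rel -= cyc * per;
      } else if (rel >= stim(k, 4)) {
        continue;
      }
      if (rel < stim(k, 4)) {
        int n0 = (int)stim(k, 0), n1 = (int)stim(k, 1);
        for (int n = n0; n <= n1; ++n) istim[n] -= stim(k, 6);  // depolarizing
        active.push_back(std::make_pair(n0, n1));
      }
    }

    for (int n = 0; n < N; ++n) {
      double* y = Y + (size_t)n * NSTATE;
      rl_step_lut(y, scals[scal_idx[n]], istim[n], eNa[n], eK[n], eCa[n]);
    }
    for (size_t a = 0; a < active.size(); ++a)
      for (int n = active[a].first; n <= active[a].second; ++n) istim[n] = 0.0;

    // diffusion step: V += dt * L V
    for (int n = 0; n < N; ++n) vold[n] = Y[(size_t)n * NSTATE];
    for (int n = 0; n < N; ++n) {
      double acc = 0.0;
      for (int p = Lptr[n]; p < Lptr[n + 1]; ++p)
        acc += Lval[p] * vold[Lidx[p]];
      dv[n] = acc;
    }
    for (int n = 0; n < N; ++n) Y[(size_t)n * NSTATE] += dt * dv[n];

    if (s % 200 == 0) {
      for (int n = 0; n < N; ++n)
        if (std::fabs(Y[(size_t)n * NSTATE]) > 200.0)
          stop("numerical blow-up at node %d, t = %f ms", n + 1, t);
    }
  }

  return List::create(_["frames"] = frames, _["times"] = ftimes,
                      _["states"] = states);
}

// node ranges in `stim` above are (row0, row1) inclusive 0-based node index
// ranges; R side converts arbitrary node sets into contiguous runs.

// ---------------------------------------------------------------------------
// EGM forward model: V_e(p, t) = k * sum_c s_c(t) * measure_c / r(p, c)
// with r clamped below at rmin. G is dense (n_points x n_cells); computing
// G then G %*% S in R would be equivalent, this keeps memory bounded.
// [[Rcpp::export]]
NumericMatrix egm_gain_cpp(NumericMatrix cells, NumericVector measure,
                           NumericMatrix points, double k, double rmin) {
  const int nc = cells.nrow(), np = points.nrow();
  NumericMatrix G(np, nc);
  for (int p = 0; p < np; ++p) {
    double px = points(p, 0), py = points(p, 1), pz = points(p, 2);
    for (int c = 0; c < nc; ++c) {
      double dx = px - cells(c, 0), dy = py - cells(c, 1), dz = pz - cells(c, 2);
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (r < rmin) r = rmin;
      G(p, c) = k * measure[c] / r;
    }
  }
  return G;
}

// ---------------------------------------------------------------------------
// Phase-singularity detection on an interpolated periodic projection.
//
// Z: complex analytic signals at electrodes (n_elec x n_frames)
// W: interpolation weights, sparse triplets (row = grid point, cols of
//    widx 0-based electrode indices, 3 per grid point)
// Grid: nlon x nlat points, periodic in lon (row-major index
//    g = ilat * nlon + ilon). Charge evaluated on each plaquette.
// Returns matrix with rows (frame_index, ilon, ilat, charge), 0-based
// plaquette lower-left corner.
// [[Rcpp::export]]
NumericMatrix projection_ps_cpp(ComplexMatrix Z, IntegerMatrix widx,
                                NumericMatrix wval, int nlon, int nlat,
                                bool periodic) {
  const int nf = Z.ncol();
  const int ng = widx.nrow();
  if (ng != nlon * nlat) stop("grid size mismatch");
  std::vector<double> ph(ng);
  std::vector<double> zr(ng), zi(ng);
  std::vector<double> out;  // frame, ilon, ilat, charge
  const double TWOPI = 2.0 * M_PI;

  for (int f = 0; f < nf; ++f) {
    for (int g = 0; g < ng; ++g) {
      double ar = 0.0, ai = 0.0;
      for (int k = 0; k < widx.ncol(); ++k) {
        int e = widx(g, k);
        if (e < 0) continue;
        Rcomplex z = Z(e, f);
        ar += wval(g, k) * z.r;
        ai += wval(g, k) * z.i;
      }
      ph[g] = std::atan2(ai, ar);
    }
    int nlon_eff = periodic ? nlon : (nlon - 1);
    for (int j = 0; j + 1 < nlat; ++j) {
      for (int i = 0; i < nlon_eff; ++i) {
        int i1 = (i + 1) % nlon;
        double p00 = ph[j * nlon + i], p10 = ph[j * nlon + i1];
        double p11 = ph[(j + 1) * nlon + i1], p01 = ph[(j + 1) * nlon + i];
        double s = 0.0, d;
        d = p10 - p00; d -= TWOPI * std::floor(d / TWOPI + 0.5); s += d;
        d = p11 - p10; d -= TWOPI * std::floor(d / TWOPI + 0.5); s += d;
        d = p01 - p11; d -= TWOPI * std::floor(d / TWOPI + 0.5); s += d;
        d = p00 - p01; d -= TWOPI * std::floor(d / TWOPI + 0.5); s += d;
        if (std::fabs(s) > TWOPI - 1e-6) {
          out.push_back(f);
          out.push_back(i);
          out.push_back(j);
          out.push_back(s > 0 ? 1.0 : -1.0);
        }
      }
    }
  }
  int nr = (int)(out.size() / 4);
  NumericMatrix M(nr, 4);
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < 4; ++c) M(r, c) = out[(size_t)r * 4 + c];
  return M;
}

// Plaquette topological charges for a phase movie on a structured grid.
// phases: (ng x n_frames), grid nlon x nlat (row-major as above).
// Same output convention as projection_ps_cpp.
// [[Rcpp::export]]
NumericMatrix grid_ps_cpp(NumericMatrix phases, int nlon, int nlat,
                          bool periodic) {
  const int nf = phases.ncol();
  if (phases.nrow() != nlon * nlat) stop("grid size mismatch");
  std::vector<double> out;
  const double TWOPI = 2.0 * M_PI;
  for (int f = 0; f < nf; ++f) {
    const double* ph = &phases(0, f);
    int nlon_eff = periodic ? nlon : (nlon - 1);
    for (int j = 0; j + 1 < nlat; ++j) {
      for (int i = 0; i < nlon_eff; ++i) {
        int i1 = (i + 1) % nlon;
        double p00 = ph[j * nlon + i], p10 = ph[j * nlon + i1];
        double p11 = ph[(j + 1) * nlon + i1], p01 = ph[(j + 1) * nlon + i];
        if (!R_finite(p00) || !R_finite(p10) || !R_finite(p11) || !R_finite(p01))
          continue;
        double s = 0.0, d;
        d = p10 - p00; d -= TWOPI * std::floor(d / TWOPI + 0.5); s += d;
        d = p11 - p10; d -= TWOPI * std::floor(d / TWOPI + 0.5); s += d;
        d = p01 - p11; d -= TWOPI * std::floor(d / TWOPI + 0.5); s += d;
        d = p00 - p01; d -= TWOPI * std::floor(d / TWOPI + 0.5); s += d;
        if (std::fabs(s) > TWOPI - 1e-6) {
          out.push_back(f);
          out.push_back(i);
          out.push_back(j);
          out.push_back(s > 0 ? 1.0 : -1.0);
        }
      }
    }
  }
  int nr = (int)(out.size() / 4);
  NumericMatrix M(nr, 4);
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < 4; ++c) M(r, c) = out[(size_t)r * 4 + c];
  return M;
}
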