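// Human ventricular myocyte model (ten Tusscher-Panfilov 2006, epicardial
// parameter set) with an added late sodium current (Hund-Rudy style mL/hL
// gating), plus a 2D anisotropic monodomain reaction-diffusion solver.
//
// Gating-rate quantities that depend only on V are tabulated once per run
// (fixed dt) on a 0.05 mV grid and linearly interpolated; concentrations,
// pumps and exchangers are evaluated directly.  Gates advance by
// Rush-Larsen exponential integration, V and concentrations by forward
// Euler; diffusion uses an explicit 9-point stencil with no-flux faces at
// inactive (background / dense-scar) nodes.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstring>
using namespace Rcpp;

// scalable parameters (order must match tt_param_names() on the R side)
enum { P_GNA, P_GK1, P_GTO, P_GKR, P_GKS, P_GCAL, P_GNAL, P_KNACA,
       P_PNAK, P_VMAXUP, P_GPCA, P_GPK, P_GBNA, P_GBCA, NPAR };

// state layout (order must match tt_state_names() on the R side)
enum { S_V, S_KI, S_NAI, S_CAI, S_CASS, S_CASR, S_M, S_H, S_J,
       S_XR1, S_XR2, S_XS, S_R, S_S, S_D, S_F, S_F2, S_FCASS,
       S_RR, S_ML, S_HL, NSTATE };

// physical constants and fixed model parameters
static const double Rgas = 8314.472, Temp = 310.0, Frdy = 96485.3415;
static const double RTF  = Rgas * Temp / Frdy;      // ~26.71 mV
static const double Ko = 5.4, Nao = 140.0, Cao = 2.0;
static const double Vc = 0.016404, Vsr = 0.001094, Vss = 0.00005468;
static const double Bufc = 0.2,  Kbufc = 0.001;
static const double Bufsr = 10.0, Kbufsr = 0.3;
static const double Bufss = 0.4,  Kbufss = 0.00025;
static const double Kup = 0.00025, Vrel = 0.102;
static const double k1p = 0.15, k2p = 0.045, k3 = 0.060, k4 = 0.005;
static const double EC = 1.5, maxsr = 2.5, minsr = 1.0;
static const double Vleak = 0.00036, Vxfer = 0.0038;
static const double pKNa = 0.03, KmK = 1.0, KmNa = 40.0;
static const double ncx_gamma = 0.35, KmCa = 1.38, KmNai = 87.5;
static const double ksat = 0.1, ncx_alpha = 2.5;
static const double CAP = 0.185;                    // membrane capacitance factor

// lookup-table slots per voltage bin: 13 gates x (inf, rl) + 5 current factors
enum { NGATE = 13 };
enum { T_INAK = 2 * NGATE, T_IPK, T_ICALE, T_NCX1, T_NCX2, NT };
static const int GATE_STATE[NGATE] =
  { S_M, S_H, S_J, S_XR1, S_XR2, S_XS, S_R, S_S, S_D, S_F, S_F2, S_ML, S_HL };

struct Tables {
  double vmin, dv, inv_dv;
  int n;
  std::vector<double> g;        // n * NT
  double kmin, inv_dk;
  int nk;
  std::vector<double> k1tab;    // xK1_inf as a function of (V - EK)
};

// gate steady states and time constants at voltage V; out[2*q] = inf,
// out[2*q+1] = tau, in GATE_STATE order
static void gate_inf_tau(double V, double* out) {
  // INa m, h, j
  double m_inf = 1.0 / std::pow(1.0 + std::exp((-56.86 - V) / 9.03), 2.0);
  double a_m = 1.0 / (1.0 + std::exp((-60.0 - V) / 5.0));
  double b_m = 0.1 / (1.0 + std::exp((V + 35.0) / 5.0)) +
               0.1 / (1.0 + std::exp((V - 50.0) / 200.0));
  double tau_m = a_m * b_m;
  double h_inf = 1.0 / std::pow(1.0 + std::exp((V + 71.55) / 7.43), 2.0);
  double a_h, b_h;
  if (V >= -40.0) {
    a_h = 0.0;
    b_h = 0.77 / (0.13 * (1.0 + std::exp(-(V + 10.66) / 11.1)));
  } else {
    a_h = 0.057 * std::exp(-(V + 80.0) / 6.8);
    b_h = 2.7 * std::exp(0.079 * V) + 3.1e5 * std::exp(0.3485 * V);
  }
  double tau_h = 1.0 / (a_h + b_h);
  double j_inf = h_inf;
  double a_j, b_j;
  if (V >= -40.0) {
    a_j = 0.0;
    b_j = 0.6 * std::exp(0.057 * V) / (1.0 + std::exp(-0.1 * (V + 32.0)));
  } else {
    a_j = (-2.5428e4 * std::exp(0.2444 * V) - 6.948e-6 * std::exp(-0.04391 * V)) *
          (V + 37.78) / (1.0 + std::exp(0.311 * (V + 79.23)));
    b_j = 0.02424 * std::exp(-0.01052 * V) /
          (1.0 + std::exp(-0.1378 * (V + 40.14)));
  }
  double tau_j = 1.0 / (a_j + b_j);
  // IKr xr1, xr2
  double xr1_inf = 1.0 / (1.0 + std::exp((-26.0 - V) / 7.0));
  double a_xr1 = 450.0 / (1.0 + std::exp((-45.0 - V) / 10.0));
  double b_xr1 = 6.0 / (1.0 + std::exp((V + 30.0) / 11.5));
  double tau_xr1 = a_xr1 * b_xr1;
  double xr2_inf = 1.0 / (1.0 + std::exp((V + 88.0) / 24.0));
  double a_xr2 = 3.0 / (1.0 + std::exp((-60.0 - V) / 20.0));
  double b_xr2 = 1.12 / (1.0 + std::exp((V - 60.0) / 20.0));
  double tau_xr2 = a_xr2 * b_xr2;
  // IKs xs
  double xs_inf = 1.0 / (1.0 + std::exp((-5.0 - V) / 14.0));
  double a_xs = 1400.0 / std::sqrt(1.0 + std::exp((5.0 - V) / 6.0));
  double b_xs = 1.0 / (1.0 + std::exp((V - 35.0) / 15.0));
  double tau_xs = a_xs * b_xs + 80.0;
  // Ito r, s (epicardial)
  double r_inf = 1.0 / (1.0 + std::exp((20.0 - V) / 6.0));
  double tau_r = 9.5 * std::exp(-(V + 40.0) * (V + 40.0) / 1800.0) + 0.8;
  double s_inf = 1.0 / (1.0 + std::exp((V + 20.0) / 5.0));
  double tau_s = 85.0 * std::exp(-(V + 45.0) * (V + 45.0) / 320.0) +
                 5.0 / (1.0 + std::exp((V - 20.0) / 5.0)) + 3.0;
  // ICaL d, f, f2 (fcass handled directly, depends on CaSS)
  double d_inf = 1.0 / (1.0 + std::exp((-8.0 - V) / 7.5));
  double a_d = 1.4 / (1.0 + std::exp((-35.0 - V) / 13.0)) + 0.25;
  double b_d = 1.4 / (1.0 + std::exp((V + 5.0) / 5.0));
  double g_d = 1.0 / (1.0 + std::exp((50.0 - V) / 20.0));
  double tau_d = a_d * b_d + g_d;
  double f_inf = 1.0 / (1.0 + std::exp((V + 20.0) / 7.0));
  double tau_f = 1102.5 * std::exp(-(V + 27.0) * (V + 27.0) / 225.0) +
                 200.0 / (1.0 + std::exp((13.0 - V) / 10.0)) +
                 180.0 / (1.0 + std::exp((V + 30.0) / 10.0)) + 20.0;
  double f2_inf = 0.67 / (1.0 + std::exp((V + 35.0) / 7.0)) + 0.33;
  double tau_f2 = 562.0 * std::exp(-(V + 27.0) * (V + 27.0) / 240.0) +
                  31.0 / (1.0 + std::exp((25.0 - V) / 10.0)) +
                  80.0 / (1.0 + std::exp((V + 30.0) / 10.0));
  // INaL mL (Hund-Rudy rates, INa-like activation), hL slow inactivation
  double dv = V + 47.13;
  double a_ml = (std::fabs(dv) < 1e-6)
      ? 3.2
      : 0.32 * dv / (1.0 - std::exp(-0.1 * dv));
  double b_ml = 0.08 * std::exp(-V / 11.0);
  double ml_inf = a_ml / (a_ml + b_ml);
  double tau_ml = 1.0 / (a_ml + b_ml);
  double hl_inf = 1.0 / (1.0 + std::exp((V + 91.0) / 6.1));
  double tau_hl = 600.0;

  const double infs[NGATE] = { m_inf, h_inf, j_inf, xr1_inf, xr2_inf, xs_inf,
                               r_inf, s_inf, d_inf, f_inf, f2_inf, ml_inf, hl_inf };
  const double taus[NGATE] = { tau_m, tau_h, tau_j, tau_xr1, tau_xr2, tau_xs,
                               tau_r, tau_s, tau_d, tau_f, tau_f2, tau_ml, tau_hl };
  for (int q = 0; q < NGATE; ++q) {
    out[2 * q]     = infs[q];
    out[2 * q + 1] = taus[q];
  }
}

static Tables make_tables(double dt) {
  Tables T;
  T.vmin = -120.0; T.dv = 0.05; T.inv_dv = 1.0 / T.dv;
  T.n = (int)((100.0 - T.vmin) / T.dv) + 2;   // V in [-120, 100]
  T.g.assign((size_t)T.n * NT, 0.0);
  double buf[2 * NGATE];
  for (int i = 0; i < T.n; ++i) {
    double V = T.vmin + i * T.dv;
    gate_inf_tau(V, buf);
    double* row = &T.g[(size_t)i * NT];
    for (int q = 0; q < NGATE; ++q) {
      row[2 * q]     = buf[2 * q];
      row[2 * q + 1] = std::exp(-dt / buf[2 * q + 1]);
    }
    row[T_INAK] = 1.0 / (1.0 + 0.1245 * std::exp(-0.1 * V / RTF) +
                         0.0353 * std::exp(-V / RTF));
    row[T_IPK]  = 1.0 / (1.0 + std::exp((25.0 - V) / 5.98));
    row[T_ICALE] = std::exp(2.0 * (V - 15.0) / RTF);
    row[T_NCX1] = std::exp(ncx_gamma * V / RTF);
    row[T_NCX2] = std::exp((ncx_gamma - 1.0) * V / RTF);
  }
  // xK1_inf over x = V - EK
  T.kmin = -250.0; T.inv_dk = 1.0 / 0.05;
  T.nk = (int)((250.0 - T.kmin) * T.inv_dk) + 2;
  T.k1tab.assign(T.nk, 0.0);
  for (int i = 0; i < T.nk; ++i) {
    double x = T.kmin + i * 0.05;
    double a = 0.1 / (1.0 + std::exp(0.06 * (x - 200.0)));
    double b = (3.0 * std::exp(0.0002 * (x + 100.0)) + std::exp(0.1 * (x - 10.0))) /
               (1.0 + std::exp(-0.5 * x));
    T.k1tab[i] = a / (a + b);
  }
  return T;
}

// one ionic step; updates state in place; istim in A/F (negative depolarizes)
static inline void ionic_step(double* S, const double* P, double dt,
                              double istim, const Tables& T) {
  double V = S[S_V];
  double u = (V - T.vmin) * T.inv_dv;
  if (u < 0.0) u = 0.0;
  if (u > T.n - 2) u = T.n - 2;
  int i0 = (int)u;
  double w = u - i0;
  const double* a = &T.g[(size_t)i0 * NT];
  const double* b = a + NT;
#define LK(k) (a[k] + w * (b[k] - a[k]))

  // Rush-Larsen gate updates
  for (int q = 0; q < NGATE; ++q) {
    double inf = LK(2 * q), rl = LK(2 * q + 1);
    double* g = &S[GATE_STATE[q]];
    *g = inf + (*g - inf) * rl;
  }
  // fcass gate (CaSS-dependent)
  {
    double css = S[S_CASS] / 0.05;
    double den = 1.0 + css * css;
    double inf = 0.6 / den + 0.4;
    double tau = 80.0 / den + 2.0;
    S[S_FCASS] = inf + (S[S_FCASS] - inf) * std::exp(-dt / tau);
  }

  double Ki = S[S_KI], Nai = S[S_NAI], Cai = S[S_CAI];
  double CaSS = S[S_CASS], CaSR = S[S_CASR];
  double EK  = RTF * std::log(Ko / Ki);
  double ENa = RTF * std::log(Nao / Nai);
  double EKs = RTF * std::log((Ko + pKNa * Nao) / (Ki + pKNa * Nai));
  double ECa = 0.5 * RTF * std::log(Cao / Cai);

  double INa  = P[P_GNA] * S[S_M] * S[S_M] * S[S_M] * S[S_H] * S[S_J] * (V - ENa);
  double INaL = P[P_GNAL] * S[S_ML] * S[S_ML] * S[S_ML] * S[S_HL] * (V - ENa);
  // IK1 via (V - EK) table
  double xk;
  {
    double uk = (V - EK - T.kmin) * T.inv_dk;
    if (uk < 0.0) uk = 0.0;
    if (uk > T.nk - 2) uk = T.nk - 2;
    int k0 = (int)uk;
    double wk = uk - k0;
    xk = T.k1tab[k0] + wk * (T.k1tab[k0 + 1] - T.k1tab[k0]);
  }
  double IK1 = P[P_GK1] * xk * (V - EK);
  double Ito = P[P_GTO] * S[S_R] * S[S_S] * (V - EK);
  double IKr = P[P_GKR] * S[S_XR1] * S[S_XR2] * (V - EK);
  double IKs = P[P_GKS] * S[S_XS] * S[S_XS] * (V - EKs);
  double ICaL;
  {
    double e2 = LK(T_ICALE);
    double vm15 = V - 15.0;
    if (std::fabs(vm15) < 1e-4) {
      ICaL = P[P_GCAL] * S[S_D] * S[S_F] * S[S_F2] * S[S_FCASS] *
             2.0 * Frdy * (0.25 * CaSS - Cao);
    } else {
      ICaL = P[P_GCAL] * S[S_D] * S[S_F] * S[S_F2] * S[S_FCASS] *
             4.0 * vm15 * (Frdy / RTF) * (0.25 * CaSS * e2 - Cao) / (e2 - 1.0);
    }
  }
  double INaCa;
  {
    double e1 = LK(T_NCX1), e2 = LK(T_NCX2);
    INaCa = P[P_KNACA] *
            (e1 * Nai * Nai * Nai * Cao - e2 * Nao * Nao * Nao * Cai * ncx_alpha) /
            ((KmNai * KmNai * KmNai + Nao * Nao * Nao) * (KmCa + Cao) *
             (1.0 + ksat * e2));
  }
  double INaK = P[P_PNAK] * Ko * Nai /
                ((Ko + KmK) * (Nai + KmNa)) * LK(T_INAK);
  double IpCa = P[P_GPCA] * Cai / (Cai + 0.0005);
  double IpK  = P[P_GPK] * LK(T_IPK) * (V - EK);
  double IbNa = P[P_GBNA] * (V - ENa);
  double IbCa = P[P_GBCA] * (V - ECa);

  // calcium subsystem
  double kCaSR = maxsr - (maxsr - minsr) / (1.0 + (EC / CaSR) * (EC / CaSR));
  double kk1 = k1p / kCaSR;
  double kk2 = k2p * kCaSR;
  {
    // RR relaxes linearly in RR for fixed CaSS: exact exponential update
    double rate = k4 + kk2 * CaSS;
    double rr_inf = k4 / rate;
    S[S_RR] = rr_inf + (S[S_RR] - rr_inf) * std::exp(-dt * rate);
  }
  double O = kk1 * CaSS * CaSS * S[S_RR] / (k3 + kk1 * CaSS * CaSS);
  double Irel  = Vrel * O * (CaSR - CaSS);
  double Ileak = Vleak * (CaSR - Cai);
  double Iup   = P[P_VMAXUP] / (1.0 + Kup * Kup / (Cai * Cai));
  double Ixfer = Vxfer * (CaSS - Cai);

  double bsr = 1.0 / (1.0 + Bufsr * Kbufsr / ((CaSR + Kbufsr) * (CaSR + Kbufsr)));
  S[S_CASR] = CaSR + dt * bsr * (Iup - Irel - Ileak);
  double bss = 1.0 / (1.0 + Bufss * Kbufss / ((CaSS + Kbufss) * (CaSS + Kbufss)));
  S[S_CASS] = CaSS + dt * bss * (-Ixfer * Vc / Vss + Irel * Vsr / Vss -
                                 ICaL * CAP / (2.0 * Vss * Frdy));
  double bc = 1.0 / (1.0 + Bufc * Kbufc / ((Cai + Kbufc) * (Cai + Kbufc)));
  S[S_CAI] = Cai + dt * bc * (-(IbCa + IpCa - 2.0 * INaCa) * CAP / (2.0 * Vc * Frdy) -
                              (Iup - Ileak) * Vsr / Vc + Ixfer);
  S[S_NAI] = Nai - dt * (INa + INaL + IbNa + 3.0 * INaK + 3.0 * INaCa) *
                       CAP / (Vc * Frdy);
  S[S_KI]  = Ki - dt * (istim + IK1 + Ito + IKr + IKs - 2.0 * INaK + IpK) *
                      CAP / (Vc * Frdy);

  double Iion = INa + INaL + IK1 + Ito + IKr + IKs + ICaL + INaCa + INaK +
                IpCa + IpK + IbNa + IbCa;
  S[S_V] = V - dt * (Iion + istim);
#undef LK
}

static void check_state_finite(const double* S, double t) {
  static const char* nm[NSTATE] = {
    "V", "Ki", "Nai", "Cai", "CaSS", "CaSR", "m", "h", "j", "xr1", "xr2",
    "xs", "r", "s", "d", "f", "f2", "fcass", "RR", "mL", "hL" };
  for (int k = 0; k < NSTATE; ++k)
    if (!std::isfinite(S[k]))
      stop("integration failure at t=%.3f ms: state variable '%s' diverged",
           t, nm[k]);
}

// [[Rcpp::export]]
int tt_n_state() { return NSTATE; }

// [[Rcpp::export]]
int tt_n_param() { return NPAR; }

// Single-cell run under a train of stimuli.
// [[Rcpp::export]]
List tt_cell_run(NumericVector params, NumericVector state,
                 double dt, double duration,
                 NumericVector stim_onsets, double stim_dur, double stim_amp,
                 double sample_ms) {
  if (params.size() != NPAR) stop("params must have length %d", NPAR);
  if (state.size() != NSTATE) stop("state must have length %d", NSTATE);
  if (dt <= 0 || dt > 0.05) stop("dt must be in (0, 0.05] ms");
  Tables T = make_tables(dt);
  std::vector<double> S(state.begin(), state.end());
  const double* P = REAL(params);
  long nstep = (long)std::ceil(duration / dt);
  int every = std::max(1, (int)std::lround(sample_ms / dt));
  long nsamp = nstep / every + 2;
  NumericVector ot(nsamp), oV(nsamp), oCai(nsamp);
  long ns = 0;
  int nstim = stim_onsets.size(), istim_idx = 0;
  for (long step = 0; step <= nstep; ++step) {
    double t = step * dt;
    if (step % every == 0 && ns < nsamp) {
      ot[ns] = t; oV[ns] = S[S_V]; oCai[ns] = S[S_CAI]; ++ns;
    }
    if (step == nstep) break;
    double istim = 0.0;
    while (istim_idx < nstim && t >= stim_onsets[istim_idx] + stim_dur)
      ++istim_idx;
    for (int q = istim_idx; q < nstim; ++q) {
      if (t < stim_onsets[q]) break;
      if (t >= stim_onsets[q] && t < stim_onsets[q] + stim_dur) { istim = stim_amp; break; }
    }
    if ((step & 1023) == 0) check_state_finite(S.data(), t);
    ionic_step(S.data(), P, dt, istim, T);
  }
  check_state_finite(S.data(), nstep * dt);
  return List::create(
    _["time"] = NumericVector(ot.begin(), ot.begin() + ns),
    _["V"]    = NumericVector(oV.begin(), oV.begin() + ns),
    _["Cai"]  = NumericVector(oCai.begin(), oCai.begin() + ns),
    _["state"] = NumericVector(S.begin(), S.end()));
}

// 2D anisotropic monodomain simulation on a structured grid.
//
// variant: length nx*ny, column-major (index = ix + nx*iy); 0 = inactive
//   (background or inexcitable dense scar), k >= 1 selects column k of
//   `params` (NPAR x nvariant).
// Dxx/Dyy/Dxy: per-node diffusion tensor entries in mm^2/ms.
// stims: list of list(nodes = 1-based grid indices, onset, dur, amp).
// state0: NSTATE x (nx*ny); inactive columns are carried through unchanged.
// Returns activation times (upstroke crossings of act_thresh), final state,
// optional V snapshots, and a quiescence flag.
// [[Rcpp::export]]
List md_run(IntegerVector variant, int nx, int ny,
            NumericMatrix params,
            NumericVector Dxx, NumericVector Dyy, NumericVector Dxy,
            double dx, double dt, double t0, double duration,
            List stims, NumericMatrix state0,
            int max_act, double act_thresh, double refrac_ms,
            bool stop_quiescent, double quiesce_v, double min_run_ms,
            double snapshot_ms) {
  const int nn = nx * ny;
  if (variant.size() != nn) stop("variant length must equal nx*ny");
  if (params.nrow() != NPAR) stop("params must have %d rows", NPAR);
  if (state0.nrow() != NSTATE || state0.ncol() != nn)
    stop("state0 must be NSTATE x nx*ny");
  if ((int)Dxx.size() != nn || (int)Dyy.size() != nn || (int)Dxy.size() != nn)
    stop("diffusion tensor fields must have length nx*ny");
  if (dt <= 0 || dt > 0.05) stop("dt must be in (0, 0.05] ms");

  // active-node compaction
  std::vector<int> gidx;            // active -> grid
  std::vector<int> aidx(nn, -1);    // grid -> active
  for (int g = 0; g < nn; ++g)
    if (variant[g] > 0) { aidx[g] = (int)gidx.size(); gidx.push_back(g); }
  const int na = (int)gidx.size();
  if (na == 0) stop("no active nodes in domain");

  // explicit-stability check (includes cross-term contribution)
  double wmax = 0.0;
  for (int g = 0; g < nn; ++g)
    if (variant[g] > 0) {
      double wloc = 2.0 * (Dxx[g] + Dyy[g]) + 2.0 * std::fabs(Dxy[g]);
      if (wloc > wmax) wmax = wloc;
    }
  if (dt * wmax / (dx * dx) > 0.95)
    stop("explicit diffusion unstable: dt*max(2(Dxx+Dyy)+2|Dxy|)/dx^2 = %.3f > 0.95",
         dt * wmax / (dx * dx));

  // neighbours (active indices, -1 if absent) and face weights
  std::vector<int> nE(na, -1), nW(na, -1), nN(na, -1), nS(na, -1),
                   nNE(na, -1), nNW(na, -1), nSE(na, -1), nSW(na, -1);
  std::vector<double> wE(na, 0.0), wW(na, 0.0), wN(na, 0.0), wS(na, 0.0);
  std::vector<double> dxyE(na, 0.0), dxyW(na, 0.0), dxyN(na, 0.0), dxyS(na, 0.0);
  const double inv_dx2 = 1.0 / (dx * dx);
  for (int k = 0; k < na; ++k) {
    int g = gidx[k];
    int ix = g % nx, iy = g / nx;
    int gE = (ix + 1 < nx) ? g + 1 : -1;
    int gW = (ix > 0) ? g - 1 : -1;
    int gN = (iy + 1 < ny) ? g + nx : -1;
    int gS = (iy > 0) ? g - nx : -1;
    if (gE >= 0 && aidx[gE] >= 0) {
      nE[k] = aidx[gE]; wE[k] = 0.5 * (Dxx[g] + Dxx[gE]); dxyE[k] = Dxy[gE];
    }
    if (gW >= 0 && aidx[gW] >= 0) {
      nW[k] = aidx[gW]; wW[k] = 0.5 * (Dxx[g] + Dxx[gW]); dxyW[k] = Dxy[gW];
    }
    if (gN >= 0 && aidx[gN] >= 0) {
      nN[k] = aidx[gN]; wN[k] = 0.5 * (Dyy[g] + Dyy[gN]); dxyN[k] = Dxy[gN];
    }
    if (gS >= 0 && aidx[gS] >= 0) {
      nS[k] = aidx[gS]; wS[k] = 0.5 * (Dyy[g] + Dyy[gS]); dxyS[k] = Dxy[gS];
    }
    int gNE = (ix + 1 < nx && iy + 1 < ny) ? g + 1 + nx : -1;
    int gNW = (ix > 0 && iy + 1 < ny) ? g - 1 + nx : -1;
    int gSE = (ix + 1 < nx && iy > 0) ? g + 1 - nx : -1;
    int gSW = (ix > 0 && iy > 0) ? g - 1 - nx : -1;
    if (gNE >= 0) nNE[k] = aidx[gNE];
    if (gNW >= 0) nNW[k] = aidx[gNW];
    if (gSE >= 0) nSE[k] = aidx[gSE];
    if (gSW >= 0) nSW[k] = aidx[gSW];
  }

  // compact state: array-of-structs (one contiguous 21-double block per
  // node) plus a mirrored contiguous V buffer for the diffusion stencil
  std::vector<double> st((size_t)NSTATE * na);
  std::vector<double> vbuf(na);
  for (int k = 0; k < na; ++k) {
    for (int s = 0; s < NSTATE; ++s)
      st[(size_t)k * NSTATE + s] = state0(s, gidx[k]);
    vbuf[k] = state0(S_V, gidx[k]);
  }
  double* Vv = vbuf.data();
  std::vector<double> lap(na, 0.0), stimbuf(na, 0.0);

  // per-node parameter pointer
  std::vector<const double*> Pn(na);
  for (int k = 0; k < na; ++k) {
    int vi = variant[gidx[k]];
    if (vi > params.ncol()) stop("variant index exceeds params columns");
    Pn[k] = &params(0, vi - 1);
  }

  // stimuli -> active-index node lists
  int nst = stims.size();
  std::vector<std::vector<int> > stim_nodes(nst);
  std::vector<double> stim_on(nst), stim_off(nst), stim_amp(nst);
  double last_stim_end = t0;
  for (int q = 0; q < nst; ++q) {
    List sq = stims[q];
    IntegerVector nd = sq["nodes"];
    double on = as<double>(sq["onset"]), du = as<double>(sq["dur"]);
    stim_on[q] = on; stim_off[q] = on + du; stim_amp[q] = as<double>(sq["amp"]);
    if (on + du > last_stim_end) last_stim_end = on + du;
    for (int j = 0; j < nd.size(); ++j) {
      int g = nd[j] - 1;
      if (g < 0 || g >= nn) stop("stimulus node out of range");
      if (aidx[g] < 0) stop("stimulus node %d is not in conducting tissue", nd[j]);
      stim_nodes[q].push_back(aidx[g]);
    }
  }

  Tables T = make_tables(dt);
  long nstep = (long)std::ceil(duration / dt);

  // activation bookkeeping
  NumericMatrix act(max_act, nn);
  std::fill(act.begin(), act.end(), NA_REAL);
  IntegerVector nact(nn, 0);
  std::vector<double> last_act(na, -1e9);

  // snapshots
  int snap_every = (snapshot_ms > 0) ? std::max(1, (int)std::lround(snapshot_ms / dt)) : 0;
  std::vector<double> snaps;
  std::vector<double> snap_t;

  bool quiescent = false;
  double t_end = t0 + nstep * dt;
  int check_every = std::max(1, (int)std::lround(2.0 / dt));

  for (long step = 0; step < nstep; ++step) {
    double t = t0 + step * dt;

    if (snap_every && step % snap_every == 0) {
      snap_t.push_back(t);
      snaps.insert(snaps.end(), Vv, Vv + na);
    }

    // diffusion (Jacobi buffer)
    for (int k = 0; k < na; ++k) {
      double vc = Vv[k];
      double vE = nE[k] >= 0 ? Vv[nE[k]] : vc;
      double vW = nW[k] >= 0 ? Vv[nW[k]] : vc;
      double vN = nN[k] >= 0 ? Vv[nN[k]] : vc;
      double vS = nS[k] >= 0 ? Vv[nS[k]] : vc;
      double l = wE[k] * (vE - vc) + wW[k] * (vW - vc) +
                 wN[k] * (vN - vc) + wS[k] * (vS - vc);
      // mixed-derivative terms (dropped where neighbours are missing)
      double vNE = nNE[k] >= 0 ? Vv[nNE[k]] : vc;
      double vNW = nNW[k] >= 0 ? Vv[nNW[k]] : vc;
      double vSE = nSE[k] >= 0 ? Vv[nSE[k]] : vc;
      double vSW = nSW[k] >= 0 ? Vv[nSW[k]] : vc;
      double cross = 0.25 * (dxyE[k] * (vNE - vSE) - dxyW[k] * (vNW - vSW) +
                             dxyN[k] * (vNE - vNW) - dxyS[k] * (vSE - vSW));
      lap[k] = (l + cross) * inv_dx2;
    }

    // stimulus currents
    bool any_stim = false;
    for (int q = 0; q < nst; ++q)
      if (t >= stim_on[q] && t < stim_off[q]) { any_stim = true; break; }
    if (any_stim) {
      std::fill(stimbuf.begin(), stimbuf.end(), 0.0);
      for (int q = 0; q < nst; ++q)
        if (t >= stim_on[q] && t < stim_off[q])
          for (size_t j = 0; j < stim_nodes[q].size(); ++j)
            stimbuf[stim_nodes[q][j]] += stim_amp[q];
    }

    // reaction step + activation detection
    for (int k = 0; k < na; ++k) {
      double vprev = Vv[k];
      double* S = &st[(size_t)k * NSTATE];
      S[S_V] = vprev + dt * lap[k];
      ionic_step(S, Pn[k], dt, any_stim ? stimbuf[k] : 0.0, T);
      Vv[k] = S[S_V];
      double vnew = Vv[k];
      if (vprev < act_thresh && vnew >= act_thresh &&
          (t - last_act[k]) > refrac_ms) {
        last_act[k] = t;
        int g = gidx[k];
        if (nact[g] < max_act) act(nact[g], g) = t;
        nact[g] += 1;
      }
    }

    if ((step % check_every) == 0) {
      double vmax = -1e9;
      for (int k = 0; k < na; ++k) if (Vv[k] > vmax) vmax = Vv[k];
      if (vmax > 200.0 || vmax < -200.0)
        stop("monodomain instability: |V| exceeded 200 mV at t=%.2f ms", t);
      if (!std::isfinite(vmax)) check_state_finite(&st[0], t);
      if (stop_quiescent && vmax < quiesce_v && t > last_stim_end + 10.0 &&
          (t - t0) >= min_run_ms) {
        quiescent = true;
        t_end = t;
        break;
      }
    }
  }

  // final full-grid state
  NumericMatrix stateF(clone(state0));
  for (int k = 0; k < na; ++k)
    for (int s = 0; s < NSTATE; ++s)
      stateF(s, gidx[k]) = st[(size_t)k * NSTATE + s];

  List out = List::create(
    _["act"] = act, _["n_act"] = nact,
    _["state"] = stateF, _["t_end"] = t_end,
    _["quiescent"] = quiescent,
    _["active"] = IntegerVector(gidx.begin(), gidx.end()));
  if (snap_every) {
    int nsn = (int)snap_t.size();
    NumericMatrix sm(na, nsn);
    for (int j = 0; j < nsn; ++j)
      for (int k = 0; k < na; ++k)
        sm(k, j) = snaps[(size_t)j * na + k];
    out["snap_v"] = sm;
    out["snap_t"] = NumericVector(snap_t.begin(), snap_t.end());
  }
  return out;
}
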