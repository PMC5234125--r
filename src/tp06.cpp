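// Human ventricular ionic model (ten Tusscher & Panfilov 2006 parameterization)
// and monodomain tissue propagation on Cartesian fixture geometries.
//
// Gates use a Rush-Larsen exponential integrator (in [0,1] by construction);
// concentrations use forward updates with analytic buffering, matching the
// model's published numerical scheme. Voltage-dependent gate coefficients are
// tabulated once per run on a fine grid and linearly interpolated, which keeps
// long tissue runs tractable while remaining fully deterministic.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
#include "rice_core.h"
using namespace Rcpp;

// ---- physical constants (units: mV, ms, mM, pA/pF) ----
static const double RGAS = 8314.472;   // mJ/(mol K)
static const double FRDY = 96485.3415; // C/mol
static const double TEMP = 310.0;      // K
static const double RTONF = RGAS * TEMP / FRDY; // ~26.71 mV
static const double CCELL = 0.185;     // whole-cell capacitance scale (uF)

// ---- parameter vector layout (kept in step with R's tp06_param_names) ----
enum ParIdx {
  P_Cm = 0, P_GNa, P_GK1, P_Gto, P_GKr, P_GKs, P_GCaL, P_kNaCa, P_PNaK,
  P_GpCa, P_GpK, P_GbCa, P_GbNa,
  P_Vmaxup, P_Vrel, P_Vleak, P_Vxfer,
  P_Ko, P_Cao, P_Nao, P_Vc, P_Vsr, P_Vss,
  P_Bufc, P_Kbufc, P_Bufsr, P_Kbufsr, P_Bufss, P_Kbufss,
  P_k1prime, P_k2prime, P_k3, P_k4, P_EC, P_maxsr, P_minsr,
  P_Kup, P_KpCa, P_KmK, P_KmNa, P_KmNai, P_KmCa, P_ksat, P_nNaCa, P_pKNa,
  NPAR
};

// ---- state vector layout (kept in step with R's tp06_state_names) ----
enum StIdx {
  S_V = 0, S_m, S_h, S_j, S_xr1, S_xr2, S_xs, S_r, S_s, S_d, S_f, S_f2,
  S_fcass, S_RR, S_Cai, S_CaSR, S_CaSS, S_Nai, S_Ki,
  NSTATE
};

// Region codes: 0 = endo, 1 = mid, 2 = epi (s-gate kinetics differ for endo).

struct GateLUT {
  double vmin, vmax, dv;
  int n;
  // inf and Rush-Larsen factor exp(-dt/tau) per voltage-dependent gate
  std::vector<double> m_inf, m_rl, h_inf, h_rl, j_inf, j_rl,
      xr1_inf, xr1_rl, xr2_inf, xr2_rl, xs_inf, xs_rl,
      r_inf, r_rl, s_inf_epi, s_rl_epi, s_inf_endo, s_rl_endo,
      d_inf, d_rl, f_inf, f_rl, f2_inf, f2_rl;
  // voltage-dependent current factors
  std::vector<double> exq;        // exp(2 (V-15) F / RT)
  std::vector<double> naca_e1;    // exp(n V F/RT)
  std::vector<double> naca_e2;    // exp((n-1) V F/RT)
  std::vector<double> rec_inak, rec_ipk;
  std::vector<double> ik1r;       // inward rectification vs (V - EK)

  inline double at(const std::vector<double>& tab, double v) const {
    double x = (v - vmin) / dv;
    if (x <= 0.0) return tab[0];
    if (x >= n - 1) return tab[n - 1];
    int i = (int)x;
    double w = x - i;
    return tab[i] + (tab[i + 1] - tab[i]) * w;
  }
};

static void build_lut(GateLUT& L, double dt, const double* p) {
  L.vmin = -150.0; L.vmax = 150.0; L.dv = 0.05;
  L.n = (int)((L.vmax - L.vmin) / L.dv) + 1;
  int n = L.n;
  const double nna = p[P_nNaCa];
  std::vector<double>* all[] = {
    &L.m_inf, &L.m_rl, &L.h_inf, &L.h_rl, &L.j_inf, &L.j_rl,
    &L.xr1_inf, &L.xr1_rl, &L.xr2_inf, &L.xr2_rl, &L.xs_inf, &L.xs_rl,
    &L.r_inf, &L.r_rl, &L.s_inf_epi, &L.s_rl_epi, &L.s_inf_endo, &L.s_rl_endo,
    &L.d_inf, &L.d_rl, &L.f_inf, &L.f_rl, &L.f2_inf, &L.f2_rl,
    &L.exq, &L.naca_e1, &L.naca_e2, &L.rec_inak, &L.rec_ipk, &L.ik1r
  };
  for (auto* v : all) v->resize(n);

  for (int i = 0; i < n; ++i) {
    double V = L.vmin + i * L.dv;

    double AM = 1.0 / (1.0 + std::exp((-60.0 - V) / 5.0));
    double BM = 0.1 / (1.0 + std::exp((V + 35.0) / 5.0)) +
                0.10 / (1.0 + std::exp((V - 50.0) / 200.0));
    double TAU_M = AM * BM;
    double M_INF = 1.0 / std::pow(1.0 + std::exp((-56.86 - V) / 9.03), 2.0);

    double AH, BH, AJ, BJ;
    if (V >= -40.0) {
      AH = 0.0;
      BH = 0.77 / (0.13 * (1.0 + std::exp(-(V + 10.66) / 11.1)));
      AJ = 0.0;
      BJ = 0.6 * std::exp(0.057 * V) / (1.0 + std::exp(-0.1 * (V + 32.0)));
    } else {
      AH = 0.057 * std::exp(-(V + 80.0) / 6.8);
      BH = 2.7 * std::exp(0.079 * V) + 3.1e5 * std::exp(0.3485 * V);
      AJ = (-2.5428e4 * std::exp(0.2444 * V) - 6.948e-6 * std::exp(-0.04391 * V)) *
           (V + 37.78) / (1.0 + std::exp(0.311 * (V + 79.23)));
      BJ = 0.02424 * std::exp(-0.01052 * V) /
           (1.0 + std::exp(-0.1378 * (V + 40.14)));
    }
    double TAU_H = 1.0 / (AH + BH);
    double H_INF = 1.0 / std::pow(1.0 + std::exp((V + 71.55) / 7.43), 2.0);
    double TAU_J = 1.0 / (AJ + BJ);
    double J_INF = H_INF;

    double Xr1_INF = 1.0 / (1.0 + std::exp((-26.0 - V) / 7.0));
    double axr1 = 450.0 / (1.0 + std::exp((-45.0 - V) / 10.0));
    double bxr1 = 6.0 / (1.0 + std::exp((V + 30.0) / 11.5));
    double TAU_Xr1 = axr1 * bxr1;

    double Xr2_INF = 1.0 / (1.0 + std::exp((V + 88.0) / 24.0));
    double axr2 = 3.0 / (1.0 + std::exp((-60.0 - V) / 20.0));
    double bxr2 = 1.12 / (1.0 + std::exp((V - 60.0) / 20.0));
    double TAU_Xr2 = axr2 * bxr2;

    double Xs_INF = 1.0 / (1.0 + std::exp((-5.0 - V) / 14.0));
    double Axs = 1400.0 / std::sqrt(1.0 + std::exp((5.0 - V) / 6.0));
    double Bxs = 1.0 / (1.0 + std::exp((V - 35.0) / 15.0));
    double TAU_Xs = Axs * Bxs + 80.0;

    double R_INF = 1.0 / (1.0 + std::exp((20.0 - V) / 6.0));
    double TAU_R = 9.5 * std::exp(-(V + 40.0) * (V + 40.0) / 1800.0) + 0.8;

    double S_INF_E = 1.0 / (1.0 + std::exp((V + 20.0) / 5.0));
    double TAU_S_E = 85.0 * std::exp(-(V + 45.0) * (V + 45.0) / 320.0) +
                     5.0 / (1.0 + std::exp((V - 20.0) / 5.0)) + 3.0;
    double S_INF_N = 1.0 / (1.0 + std::exp((V + 28.0) / 5.0));
    double TAU_S_N = 1000.0 * std::exp(-(V + 67.0) * (V + 67.0) / 1000.0) + 8.0;

    double D_INF = 1.0 / (1.0 + std::exp((-8.0 - V) / 7.5));
    double Ad = 1.4 / (1.0 + std::exp((-35.0 - V) / 13.0)) + 0.25;
    double Bd = 1.4 / (1.0 + std::exp((V + 5.0) / 5.0));
    double Cd = 1.0 / (1.0 + std::exp((50.0 - V) / 20.0));
    double TAU_D = Ad * Bd + Cd;

    double F_INF = 1.0 / (1.0 + std::exp((V + 20.0) / 7.0));
    double Af = 1102.5 * std::exp(-(V + 27.0) * (V + 27.0) / 225.0);
    double Bf = 200.0 / (1.0 + std::exp((13.0 - V) / 10.0));
    double Cf = 180.0 / (1.0 + std::exp((V + 30.0) / 10.0)) + 20.0;
    double TAU_F = Af + Bf + Cf;

    double F2_INF = 0.67 / (1.0 + std::exp((V + 35.0) / 7.0)) + 0.33;
    double Af2 = 600.0 * std::exp(-(V + 25.0) * (V + 25.0) / 170.0);
    double Bf2 = 31.0 / (1.0 + std::exp((25.0 - V) / 10.0));
    double Cf2 = 16.0 / (1.0 + std::exp((V + 30.0) / 10.0));
    double TAU_F2 = Af2 + Bf2 + Cf2;

    L.m_inf[i] = M_INF;      L.m_rl[i] = std::exp(-dt / TAU_M);
    L.h_inf[i] = H_INF;      L.h_rl[i] = std::exp(-dt / TAU_H);
    L.j_inf[i] = J_INF;      L.j_rl[i] = std::exp(-dt / TAU_J);
    L.xr1_inf[i] = Xr1_INF;  L.xr1_rl[i] = std::exp(-dt / TAU_Xr1);
    L.xr2_inf[i] = Xr2_INF;  L.xr2_rl[i] = std::exp(-dt / TAU_Xr2);
    L.xs_inf[i] = Xs_INF;    L.xs_rl[i] = std::exp(-dt / TAU_Xs);
    L.r_inf[i] = R_INF;      L.r_rl[i] = std::exp(-dt / TAU_R);
    L.s_inf_epi[i] = S_INF_E;   L.s_rl_epi[i] = std::exp(-dt / TAU_S_E);
    L.s_inf_endo[i] = S_INF_N;  L.s_rl_endo[i] = std::exp(-dt / TAU_S_N);
    L.d_inf[i] = D_INF;      L.d_rl[i] = std::exp(-dt / TAU_D);
    L.f_inf[i] = F_INF;      L.f_rl[i] = std::exp(-dt / TAU_F);
    L.f2_inf[i] = F2_INF;    L.f2_rl[i] = std::exp(-dt / TAU_F2);

    L.exq[i] = std::exp(2.0 * (V - 15.0) / RTONF);
    L.naca_e1[i] = std::exp(nna * V / RTONF);
    L.naca_e2[i] = std::exp((nna - 1.0) * V / RTONF);
    L.rec_inak[i] = 1.0 / (1.0 + 0.1245 * std::exp(-0.1 * V / RTONF) +
                           0.0353 * std::exp(-V / RTONF));
    L.rec_ipk[i] = 1.0 / (1.0 + std::exp((25.0 - V) / 5.98));

    // ik1r is indexed by (V - EK) over the same grid
    double x = V;
    double Ak1 = 0.1 / (1.0 + std::exp(0.06 * (x - 200.0)));
    double Bk1 = (3.0 * std::exp(0.0002 * (x + 100.0)) + std::exp(0.1 * (x - 10.0))) /
                 (1.0 + std::exp(-0.5 * x));
    L.ik1r[i] = Ak1 / (Ak1 + Bk1);
  }
}

// Membrane currents at the given state. `cur` (length 16) receives
// INa, IK1, Ito, IKr, IKs, ICaL, INaCa, INaK, IpCa, IpK, IbCa, IbNa,
// Ileak, Iup, Irel, Ixfer.
static inline void currents_at(const double* y, const double* p, int region,
                               const GateLUT& L, double* cur) {
  double V = y[S_V];
  double Ek = RTONF * std::log(p[P_Ko] / y[S_Ki]);
  double Ena = RTONF * std::log(p[P_Nao] / y[S_Nai]);
  double Eks = RTONF * std::log((p[P_Ko] + p[P_pKNa] * p[P_Nao]) /
                                (y[S_Ki] + p[P_pKNa] * y[S_Nai]));
  double Eca = 0.5 * RTONF * std::log(p[P_Cao] / y[S_Cai]);

  double INa = p[P_GNa] * y[S_m] * y[S_m] * y[S_m] * y[S_h] * y[S_j] * (V - Ena);

  double exq = L.at(L.exq, V);
  double den = exq - 1.0;
  double ICaL;
  if (std::fabs(den) < 1e-9) {
    // series limit at V = 15 mV
    ICaL = p[P_GCaL] * y[S_d] * y[S_f] * y[S_f2] * y[S_fcass] * 2.0 * FRDY *
           (0.25 * y[S_CaSS] - p[P_Cao]);
  } else {
    ICaL = p[P_GCaL] * y[S_d] * y[S_f] * y[S_f2] * y[S_fcass] * 4.0 *
           (V - 15.0) * (FRDY / RTONF) *
           (0.25 * y[S_CaSS] * exq - p[P_Cao]) / den;
  }

  double Gto = p[P_Gto];
  double Ito = Gto * y[S_r] * y[S_s] * (V - Ek);
  double IKr = p[P_GKr] * std::sqrt(p[P_Ko] / 5.4) * y[S_xr1] * y[S_xr2] * (V - Ek);
  double IKs = p[P_GKs] * y[S_xs] * y[S_xs] * (V - Eks);
  double IK1 = p[P_GK1] * L.at(L.ik1r, V - Ek) * (V - Ek);

  double Nai3 = y[S_Nai] * y[S_Nai] * y[S_Nai];
  double Nao3 = p[P_Nao] * p[P_Nao] * p[P_Nao];
  double INaCa = p[P_kNaCa] *
      (1.0 / (p[P_KmNai] * p[P_KmNai] * p[P_KmNai] + Nao3)) *
      (1.0 / (p[P_KmCa] + p[P_Cao])) *
      (1.0 / (1.0 + p[P_ksat] * L.at(L.naca_e2, V))) *
      (L.at(L.naca_e1, V) * Nai3 * p[P_Cao] -
       L.at(L.naca_e2, V) * Nao3 * y[S_Cai] * 2.5);

  double INaK = p[P_PNaK] * (p[P_Ko] / (p[P_Ko] + p[P_KmK])) *
                (y[S_Nai] / (y[S_Nai] + p[P_KmNa])) * L.at(L.rec_inak, V);
  double IpCa = p[P_GpCa] * y[S_Cai] / (p[P_KpCa] + y[S_Cai]);
  double IpK = p[P_GpK] * L.at(L.rec_ipk, V) * (V - Ek);
  double IbNa = p[P_GbNa] * (V - Ena);
  double IbCa = p[P_GbCa] * (V - Eca);

  // SR fluxes
  double kCaSR = p[P_maxsr] - (p[P_maxsr] - p[P_minsr]) /
                 (1.0 + (p[P_EC] / y[S_CaSR]) * (p[P_EC] / y[S_CaSR]));
  double k1 = p[P_k1prime] / kCaSR;
  double sOO = k1 * y[S_CaSS] * y[S_CaSS] * y[S_RR] /
               (p[P_k3] + k1 * y[S_CaSS] * y[S_CaSS]);
  double Irel = p[P_Vrel] * sOO * (y[S_CaSR] - y[S_CaSS]);
  double Ileak = p[P_Vleak] * (y[S_CaSR] - y[S_Cai]);
  double Iup = p[P_Vmaxup] / (1.0 + (p[P_Kup] * p[P_Kup]) / (y[S_Cai] * y[S_Cai]));
  double Ixfer = p[P_Vxfer] * (y[S_CaSS] - y[S_Cai]);

  cur[0] = INa;  cur[1] = IK1;  cur[2] = Ito;  cur[3] = IKr;
  cur[4] = IKs;  cur[5] = ICaL; cur[6] = INaCa; cur[7] = INaK;
  cur[8] = IpCa; cur[9] = IpK;  cur[10] = IbCa; cur[11] = IbNa;
  cur[12] = Ileak; cur[13] = Iup; cur[14] = Irel; cur[15] = Ixfer;
  (void)region;
}

// One reaction step (Rush-Larsen gates + forward concentrations).
// Updates y in place; returns Iion (sum of the 12 membrane currents).
static inline double react_step(double* y, const double* p, int region,
                                const GateLUT& L, double Istim, double dt) {
  double cur[16];
  currents_at(y, p, region, L, cur);
  double Iion = cur[0] + cur[1] + cur[2] + cur[3] + cur[4] + cur[5] + cur[6] +
                cur[7] + cur[8] + cur[9] + cur[10] + cur[11];
  double V = y[S_V];
  double ICaL = cur[5], INaCa = cur[6], INaK = cur[7];
  double Ileak = cur[12], Iup = cur[13], Irel = cur[14], Ixfer = cur[15];

  // ionic concentration updates (forward Euler with analytic buffering)
  double invVcF2 = 1.0 / (2.0 * p[P_Vc] * FRDY);
  double invVcF = 1.0 / (p[P_Vc] * FRDY);
  double invVssF2 = 1.0 / (2.0 * p[P_Vss] * FRDY);

  double CaCSQN = p[P_Bufsr] * y[S_CaSR] / (y[S_CaSR] + p[P_Kbufsr]);
  double dCaSR = dt * (Iup - Irel - Ileak);
  double bjsr = p[P_Bufsr] - CaCSQN - dCaSR - y[S_CaSR] + p[P_Kbufsr];
  double cjsr = p[P_Kbufsr] * (CaCSQN + dCaSR + y[S_CaSR]);
  double CaSRn = (std::sqrt(bjsr * bjsr + 4.0 * cjsr) - bjsr) / 2.0;

  double CaSSBuf = p[P_Bufss] * y[S_CaSS] / (y[S_CaSS] + p[P_Kbufss]);
  double dCaSS = dt * (-Ixfer * (p[P_Vc] / p[P_Vss]) +
                       Irel * (p[P_Vsr] / p[P_Vss]) +
                       (-ICaL * invVssF2 * CCELL));
  double bcss = p[P_Bufss] - CaSSBuf - dCaSS - y[S_CaSS] + p[P_Kbufss];
  double ccss = p[P_Kbufss] * (CaSSBuf + dCaSS + y[S_CaSS]);
  double CaSSn = (std::sqrt(bcss * bcss + 4.0 * ccss) - bcss) / 2.0;

  double CaBuf = p[P_Bufc] * y[S_Cai] / (y[S_Cai] + p[P_Kbufc]);
  double dCai = dt * ((-(cur[10] + cur[8] - 2.0 * INaCa) * invVcF2 * CCELL) -
                      (Iup - Ileak) * (p[P_Vsr] / p[P_Vc]) + Ixfer);
  double bc = p[P_Bufc] - CaBuf - dCai - y[S_Cai] + p[P_Kbufc];
  double cc = p[P_Kbufc] * (CaBuf + dCai + y[S_Cai]);
  double Cain = (std::sqrt(bc * bc + 4.0 * cc) - bc) / 2.0;

  double dNai = -(cur[0] + cur[11] + 3.0 * INaK + 3.0 * INaCa) * invVcF * CCELL;
  double dKi = -(Istim + cur[1] + cur[2] + cur[3] + cur[4] - 2.0 * INaK + cur[9]) *
               invVcF * CCELL;

  // RyR gate: linear in RR -> exponential update (stays in [0,1])
  double kCaSR = p[P_maxsr] - (p[P_maxsr] - p[P_minsr]) /
                 (1.0 + (p[P_EC] / y[S_CaSR]) * (p[P_EC] / y[S_CaSR]));
  double k2 = p[P_k2prime] * kCaSR;
  double arr = p[P_k4];
  double brr = p[P_k4] + k2 * y[S_CaSS];
  double RRinf = arr / brr;
  double RRn = RRinf + (y[S_RR] - RRinf) * std::exp(-dt * brr);

  // fcass gate (CaSS-dependent)
  double css = y[S_CaSS] / 0.05;
  double FCaSS_INF = 0.6 / (1.0 + css * css) + 0.4;
  double TAU_FCaSS = 80.0 / (1.0 + css * css) + 2.0;
  y[S_fcass] = FCaSS_INF + (y[S_fcass] - FCaSS_INF) * std::exp(-dt / TAU_FCaSS);

  // voltage-dependent gates via Rush-Larsen
  y[S_m] = L.at(L.m_inf, V) + (y[S_m] - L.at(L.m_inf, V)) * L.at(L.m_rl, V);
  y[S_h] = L.at(L.h_inf, V) + (y[S_h] - L.at(L.h_inf, V)) * L.at(L.h_rl, V);
  y[S_j] = L.at(L.j_inf, V) + (y[S_j] - L.at(L.j_inf, V)) * L.at(L.j_rl, V);
  y[S_xr1] = L.at(L.xr1_inf, V) + (y[S_xr1] - L.at(L.xr1_inf, V)) * L.at(L.xr1_rl, V);
  y[S_xr2] = L.at(L.xr2_inf, V) + (y[S_xr2] - L.at(L.xr2_inf, V)) * L.at(L.xr2_rl, V);
  y[S_xs] = L.at(L.xs_inf, V) + (y[S_xs] - L.at(L.xs_inf, V)) * L.at(L.xs_rl, V);
  y[S_r] = L.at(L.r_inf, V) + (y[S_r] - L.at(L.r_inf, V)) * L.at(L.r_rl, V);
  if (region == 0) {
    y[S_s] = L.at(L.s_inf_endo, V) + (y[S_s] - L.at(L.s_inf_endo, V)) * L.at(L.s_rl_endo, V);
  } else {
    y[S_s] = L.at(L.s_inf_epi, V) + (y[S_s] - L.at(L.s_inf_epi, V)) * L.at(L.s_rl_epi, V);
  }
  y[S_d] = L.at(L.d_inf, V) + (y[S_d] - L.at(L.d_inf, V)) * L.at(L.d_rl, V);
  y[S_f] = L.at(L.f_inf, V) + (y[S_f] - L.at(L.f_inf, V)) * L.at(L.f_rl, V);
  y[S_f2] = L.at(L.f2_inf, V) + (y[S_f2] - L.at(L.f2_inf, V)) * L.at(L.f2_rl, V);

  y[S_CaSR] = CaSRn;
  y[S_CaSS] = CaSSn;
  y[S_Cai] = Cain;
  y[S_Nai] += dt * dNai;
  y[S_Ki] += dt * dKi;
  y[S_RR] = RRn;
  y[S_V] = V - dt * (Iion + Istim);
  return Iion;
}

// [[Rcpp::export]]
NumericVector tp06_currents_cpp(NumericVector state, NumericVector params,
                                int region) {
  if (state.size() != NSTATE) stop("state must have %d entries", NSTATE);
  if (params.size() != NPAR) stop("params must have %d entries", NPAR);
  GateLUT L;
  build_lut(L, 0.02, REAL(params)); // dt irrelevant for current evaluation
  double cur[16];
  currents_at(REAL(state), REAL(params), region, L, cur);
  NumericVector out(16);
  for (int i = 0; i < 16; ++i) out[i] = cur[i];
  out.attr("names") = CharacterVector::create(
      "I_Na", "I_K1", "I_to", "I_Kr", "I_Ks", "I_CaL", "I_NaCa", "I_NaK",
      "I_pCa", "I_pK", "I_bCa", "I_bNa", "I_leak", "I_up", "I_rel", "I_xfer");
  return out;
}

// [[Rcpp::export]]
List tp06_step_cpp(NumericVector state, NumericVector params, int region,
                   double Istim, double dt) {
  if (state.size() != NSTATE) stop("state must have %d entries", NSTATE);
  GateLUT L;
  build_lut(L, dt, REAL(params));
  NumericVector y = clone(state);
  double Iion = react_step(REAL(y), REAL(params), region, L, Istim, dt);
  return List::create(_["state"] = y, _["I_ion"] = Iion);
}

// Paced single-cell run.
// [[Rcpp::export]]
List tp06_run_cell_cpp(NumericVector state0, NumericVector params, int region,
                       double cl, double stim_amp, double stim_dur,
                       double stim_onset, int n_beats, double dt,
                       int sample_every, bool record_currents) {
  GateLUT L;
  build_lut(L, dt, REAL(params));
  std::vector<double> y(REAL(state0), REAL(state0) + NSTATE);
  long nsteps = (long)std::llround(n_beats * cl / dt);
  int nsamp = (int)(nsteps / sample_every) + 1;
  NumericVector t_out(nsamp), v_out(nsamp), cai_out(nsamp);
  NumericMatrix cur_out = record_currents ? NumericMatrix(16, nsamp)
                                          : NumericMatrix(0, 0);
  // per-step diagnostics: gate range and concentration minima
  double gmin = 1.0, gmax = 0.0, cmin = 1e30;
  int blow_beat = -1;
  int k = 0;
  double cur[16];
  for (long s = 0; s <= nsteps; ++s) {
    double t = s * dt;
    if (s % sample_every == 0 && k < nsamp) {
      t_out[k] = t; v_out[k] = y[S_V]; cai_out[k] = y[S_Cai];
      if (record_currents) {
        currents_at(y.data(), REAL(params), region, L, cur);
        for (int c = 0; c < 16; ++c) cur_out(c, k) = cur[c];
      }
      ++k;
    }
    if (s == nsteps) break;
    double phase = pos_fmod(t, cl);
    double Istim = (phase >= stim_onset && phase < stim_onset + stim_dur)
                       ? stim_amp : 0.0;
    react_step(y.data(), REAL(params), region, L, Istim, dt);
    for (int g = S_m; g <= S_RR; ++g) {
      if (y[g] < gmin) gmin = y[g];
      if (y[g] > gmax) gmax = y[g];
    }
    for (int c = S_Cai; c <= S_Ki; ++c) if (y[c] < cmin) cmin = y[c];
    if (std::fabs(y[S_V]) > 200.0) { blow_beat = (int)(t / cl) + 1; break; }
  }
  NumericVector yfin(NSTATE);
  for (int i = 0; i < NSTATE; ++i) yfin[i] = y[i];
  return List::create(
      _["time"] = t_out, _["V"] = v_out, _["Ca_i"] = cai_out,
      _["currents"] = cur_out, _["final_state"] = yfin,
      _["gate_min"] = gmin, _["gate_max"] = gmax, _["conc_min"] = cmin,
      _["blowup_beat"] = blow_beat);
}

// Monodomain tissue run with per-cycle activation-time extraction.
//
// state0: NSTATE x n matrix; region: length n; params: NPAR x 3 (endo/mid/epi);
// nbr: n x 6 integer matrix of 0-based neighbour indices (-1 = boundary);
// dcoef: length-3 diffusion coefficients already divided by dx^2 per axis
//        (units ms^-1); stim_*: per-site node index / within-cycle onset.
// Activation time of a stimulus-site node is defined as its commanded onset
// (Purkinje-surrogate convention); other nodes use first upward threshold
// crossing (linearly interpolated) per cycle.
// [[Rcpp::export]]
List tp06_run_tissue_cpp(NumericMatrix state0, IntegerVector region,
                         NumericMatrix params, IntegerMatrix nbr,
                         NumericVector dcoef,
                         IntegerVector stim_nodes, NumericVector stim_onsets,
                         double stim_delay, double stim_amp, double stim_dur,
                         double cl, double duration, double dt,
                         double threshold,
                         IntegerVector probe_nodes, int probe_every,
                         bool site_onset_as_eat) {
  int n = state0.ncol();
  if (state0.nrow() != NSTATE) stop("state0 must have %d rows", NSTATE);
  GateLUT L;
  build_lut(L, dt, REAL(params)); // nNaCa shared across regions
  std::vector<double> Y(REAL(state0), REAL(state0) + (size_t)NSTATE * n);
  const double* pbase = REAL(params);
  const int* nb = INTEGER(nbr);
  long nsteps = (long)std::llround(duration / dt);
  int ncycles = (int)std::ceil(duration / cl);

  NumericMatrix eat(n, ncycles);
  std::fill(eat.begin(), eat.end(), NA_REAL);

  int npr = probe_nodes.size();
  int nprsamp = npr > 0 ? (int)((nsteps - 1) / probe_every) + 1 : 0;
  NumericMatrix ptrace(npr, nprsamp);
  NumericVector ptime(nprsamp);

  std::vector<double> Vold(n), stim(n, 0.0);
  std::vector<char> is_site(n, 0);
  for (int s = 0; s < stim_nodes.size(); ++s) is_site[stim_nodes[s]] = 1;

  int pk = 0;
  int blow_step = -1;
  for (long st = 0; st < nsteps; ++st) {
    double t = st * dt;
    double phase = pos_fmod(t, cl);
    // stimulus assembly
    std::fill(stim.begin(), stim.end(), 0.0);
    for (int s = 0; s < stim_nodes.size(); ++s) {
      double on = stim_onsets[s] + stim_delay;
      if (phase >= on && phase < on + stim_dur) stim[stim_nodes[s]] = stim_amp;
    }
    if (npr > 0 && st % probe_every == 0) {
      ptime[pk] = t;
      for (int q = 0; q < npr; ++q) ptrace(q, pk) = Y[(size_t)NSTATE * probe_nodes[q] + S_V];
      ++pk;
    }
    for (int i = 0; i < n; ++i) Vold[i] = Y[(size_t)NSTATE * i + S_V];
    // reaction
    for (int i = 0; i < n; ++i) {
      react_step(&Y[(size_t)NSTATE * i], pbase + NPAR * region[i], region[i],
                 L, stim[i], dt);
    }
    // diffusion on V (no-flux boundaries via missing neighbours)
    for (int i = 0; i < n; ++i) {
      double acc = 0.0;
      double vi = Vold[i];
      for (int a = 0; a < 3; ++a) {
        // nbr is column-major: column 2a is the low-side neighbour on axis a
        int jm = nb[i + (size_t)n * (2 * a)];
        int jp = nb[i + (size_t)n * (2 * a + 1)];
        double d = dcoef[a];
        if (d == 0.0) continue;
        if (jm >= 0) acc += d * (Vold[jm] - vi);
        if (jp >= 0) acc += d * (Vold[jp] - vi);
      }
      Y[(size_t)NSTATE * i + S_V] += dt * acc;
    }
    // activation detection
    double tnew = t + dt;
    for (int i = 0; i < n; ++i) {
      double vn = Y[(size_t)NSTATE * i + S_V];
      if (Vold[i] < threshold && vn >= threshold) {
        double tc = t + dt * (threshold - Vold[i]) / (vn - Vold[i]);
        int cyc = (int)(tc / cl);
        if (cyc < ncycles && NumericVector::is_na(eat(i, cyc)))
          eat(i, cyc) = tc - cyc * cl;
      }
      if (std::fabs(vn) > 200.0 && blow_step < 0) blow_step = (int)st;
    }
    if (blow_step >= 0) break;
    (void)tnew;
  }
  // Purkinje-surrogate convention: site activation time = commanded onset
  if (site_onset_as_eat) {
    for (int c = 0; c < ncycles; ++c)
      for (int s = 0; s < stim_nodes.size(); ++s)
        eat(stim_nodes[s], c) = stim_onsets[s];
  }
  NumericMatrix yfin(NSTATE, n);
  std::copy(Y.begin(), Y.end(), yfin.begin());
  return List::create(
      _["eat"] = eat, _["final_state"] = yfin,
      _["probe_time"] = ptime, _["probe_V"] = ptrace,
      _["blowup_step"] = blow_step, _["n_cycles"] = ncycles);
}
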