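// Shared myofilament core: state/parameter layout and single-step update.
#ifndef CARDIOMECH_RICE_CORE_H
#define CARDIOMECH_RICE_CORE_H

#include <cmath>
#include <algorithm>

enum RPar {
  R_kon = 0, R_koffL, R_koffH, R_perm50, R_nperm, R_knp, R_kpn,
  R_fapp, R_gapp, R_gslmod, R_hf, R_hfmdc, R_hb, R_gxb, R_sigmap, R_sigman,
  R_x0, R_xPsi, R_len_thick, R_len_hbare, R_len_thin, R_SLmin, R_SLmax,
  NRPAR
};

enum RSt { M_N = 0, M_P, M_PreR, M_PostR, M_TropCaL, M_TropCaH,
           M_xPreR, M_xPostR, NRST };

struct Overlap { double thick, thin; };

// positive modulo without libm's fmod (keeps the binary portable across
// glibc symbol versions)
static inline double pos_fmod(double x, double y) {
  double r = x - y * std::floor(x / y);
  if (r >= y) r -= y;
  return r < 0.0 ? r + y : r;
}

static inline Overlap sovf(double SL, const double* p) {
  double ze = std::min(p[R_len_thick] / 2.0, SL / 2.0);
  double cle = std::max(SL / 2.0 - (SL - p[R_len_thin]), p[R_len_hbare] / 2.0);
  double lo = std::max(ze - cle, 0.0);
  Overlap o;
  o.thick = lo * 2.0 / (p[R_len_thick] - p[R_len_hbare]);
  o.thin = lo / p[R_len_thin];
  return o;
}

// One myofilament step; rates in params are s^-1 (kon: uM^-1 s^-1), dt in ms,
// Ca in uM. Pool states advance by forward Euler (exactly conservative);
// troponin/strain equations, linear in their own variable, use exponential
// updates. Updates y in place; returns gxbT (s^-1).
static inline double rice_step_core(double* y, const double* p, double Ca,
                                    double SL, double dSLdt, double dt) {
  double dts = dt * 1e-3; // seconds
  Overlap o = sovf(SL, p);

  {
    double a = p[R_kon] * Ca, bL = a + p[R_koffL], bH = a + p[R_koffH];
    double infL = a / bL, infH = a / bH;
    y[M_TropCaL] = infL + (y[M_TropCaL] - infL) * std::exp(-dts * bL);
    y[M_TropCaH] = infH + (y[M_TropCaH] - infH) * std::exp(-dts * bH);
  }
  double trop_reg = (1.0 - o.thin) * y[M_TropCaL] + o.thin * y[M_TropCaH];
  double permtot = std::sqrt(1.0 / (1.0 + std::pow(p[R_perm50] / std::max(trop_reg, 1e-12),
                                                   p[R_nperm])));
  double inprmt = std::min(1.0 / permtot, 100.0);

  double knpT = p[R_knp] * permtot;
  double kpnT = p[R_kpn] * inprmt;
  double fappT = p[R_fapp];
  double gappT = p[R_gapp] * (1.0 + (1.0 - o.thick) * p[R_gslmod]);
  double x0 = p[R_x0];
  double hfmd = std::exp(-((y[M_xPreR] >= 0.0) ? 1.0 : -1.0) * p[R_hfmdc] *
                         (y[M_xPreR] / x0) * (y[M_xPreR] / x0));
  hfmd = std::min(hfmd, 2.0); // numeric guard at large negative strain
  double hfT = p[R_hf] * hfmd;
  double hbT = p[R_hb];
  double gxbmd = (y[M_xPostR] < x0)
      ? std::exp(p[R_sigmap] * ((x0 - y[M_xPostR]) / x0) * ((x0 - y[M_xPostR]) / x0))
      : std::exp(p[R_sigman] * ((y[M_xPostR] - x0) / x0) * ((y[M_xPostR] - x0) / x0));
  double gxbT = p[R_gxb] * gxbmd;

  double N = y[M_N], P = y[M_P], A1 = y[M_PreR], A2 = y[M_PostR];
  double fNP = dts * (knpT * N - kpnT * P);
  double fPA1 = dts * (fappT * P - gappT * A1);
  double fA1A2 = dts * (hfT * A1 - hbT * A2);
  double fA2P = dts * (gxbT * A2);
  y[M_N] = N - fNP;
  y[M_P] = P + fNP - fPA1 + fA2P;
  y[M_PreR] = A1 + fPA1 - fA1A2;
  y[M_PostR] = A2 + fA1A2 - fA2P;

  double fp = p[R_fapp], gp = p[R_gapp], hh = p[R_hf], hbb = p[R_hb], gg = p[R_gxb];
  double denom = fp * hh + gg * hh + gg * gp + hbb * fp + hbb * gp + gg * fp;
  double dutyPreR = (hbb * fp + gg * fp) / denom;
  double dutyPostR = fp * hh / denom;
  {
    double c = p[R_xPsi] / dutyPreR;
    double B = c * (fappT + hbT) * 1e-3;          // ms^-1
    double A = 0.5 * dSLdt + c * hbT * 1e-3 * (y[M_xPostR] - x0);
    double xinf = A / B;
    y[M_xPreR] = xinf + (y[M_xPreR] - xinf) * std::exp(-dt * B);
  }
  {
    double c = p[R_xPsi] / dutyPostR;
    double B = c * hfT * 1e-3;                    // ms^-1
    double A = 0.5 * dSLdt + c * hfT * 1e-3 * (y[M_xPreR] + x0);
    double xinf = A / B;
    y[M_xPostR] = xinf + (y[M_xPostR] - xinf) * std::exp(-dt * B);
  }
  return gxbT;
}

static inline double rice_tension(const double* y, const double* p, double SL) {
  Overlap o = sovf(SL, p);
  double fp = p[R_fapp], gp = p[R_gapp], hh = p[R_hf], hbb = p[R_hb], gg = p[R_gxb];
  double denom = fp * hh + gg * hh + gg * gp + hbb * fp + hbb * gp + gg * fp;
  double dutyPostR = fp * hh / denom;
  return o.thick * (y[M_PreR] * y[M_xPreR] + y[M_PostR] * y[M_xPostR]) /
         (p[R_x0] * dutyPostR);
}

#endif
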