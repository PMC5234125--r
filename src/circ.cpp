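// Lumped circulatory loop: a thin-wall ventricle surrogate for each ventricle
// driven by an ensemble of myofilament instances (one per activation-map
// sample, shifted by its electrical activation time), coupled to two series
// Windkessel compartments per circulation with ideal-diode valves.
//
// Flow convention: LV -> aortic valve -> systemic arterial -> Rsys ->
// systemic venous -> tricuspid -> RV -> pulmonic valve -> pulmonic arterial ->
// Rpul -> pulmonic venous -> mitral -> LV. Volumes update by inflow minus
// outflow, so total blood volume is conserved to round-off.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include "rice_core.h"
using namespace Rcpp;

enum CPar { C_Rav = 0, C_Rsys, C_Rtv, C_Rpuv, C_Rpul, C_Rmv,
            C_Csa, C_Csv, C_Cpa, C_Cpv, C_V0sa, C_V0sv, C_V0pa, C_V0pv,
            NCPAR };
enum VPar { V_B = 0, V_kappa, V_Vrest, V_alpha, V_Vref, NVPAR };
enum Vol { W_lv = 0, W_rv, W_sa, W_sv, W_pa, W_pv, NVOL };

static inline double vent_pressure(double V, double Tbar, const double* vp) {
  double ppas = vp[V_B] * std::expm1(vp[V_kappa] * (V - vp[V_Vrest]));
  double pact = vp[V_alpha] * std::max(Tbar, 0.0) *
                std::pow(V / vp[V_Vref], -2.0 / 3.0);
  return ppas + pact;
}

// One Windkessel/valve step shared by the R-facing single step and the engine.
// vol is updated in place; flows/pressures/valves written to out arrays.
static inline void circ_step_core(double* vol, const double* cp,
                                  double Plv, double Prv, double dt_ms,
                                  double* Q, double* P, int* valve) {
  double Psa = (vol[W_sa] - cp[C_V0sa]) / cp[C_Csa];
  double Psv = (vol[W_sv] - cp[C_V0sv]) / cp[C_Csv];
  double Ppa = (vol[W_pa] - cp[C_V0pa]) / cp[C_Cpa];
  double Ppv = (vol[W_pv] - cp[C_V0pv]) / cp[C_Cpv];

  double Qav = (Plv > Psa) ? (Plv - Psa) / cp[C_Rav] : 0.0;
  double Qsys = (Psa - Psv) / cp[C_Rsys];
  double Qtv = (Psv > Prv) ? (Psv - Prv) / cp[C_Rtv] : 0.0;
  double Qpuv = (Prv > Ppa) ? (Prv - Ppa) / cp[C_Rpuv] : 0.0;
  double Qpul = (Ppa - Ppv) / cp[C_Rpul];
  double Qmv = (Ppv > Plv) ? (Ppv - Plv) / cp[C_Rmv] : 0.0;

  double h = dt_ms * 1e-3; // flows are mL/s
  vol[W_lv] += h * (Qmv - Qav);
  vol[W_sa] += h * (Qav - Qsys);
  vol[W_sv] += h * (Qsys - Qtv);
  vol[W_rv] += h * (Qtv - Qpuv);
  vol[W_pa] += h * (Qpuv - Qpul);
  vol[W_pv] += h * (Qpul - Qmv);

  Q[0] = Qav; Q[1] = Qsys; Q[2] = Qtv; Q[3] = Qpuv; Q[4] = Qpul; Q[5] = Qmv;
  P[0] = Psa; P[1] = Psv; P[2] = Ppa; P[3] = Ppv;
  valve[0] = Qav > 0.0; valve[1] = Qmv > 0.0;
  valve[2] = Qtv > 0.0; valve[3] = Qpuv > 0.0;
}

// [[Rcpp::export]]
List circ_step_cpp(NumericVector volumes, NumericVector cpars,
                   double P_lv, double P_rv, double dt) {
  if (volumes.size() != NVOL) stop("volumes must have %d entries", NVOL);
  if (cpars.size() != NCPAR) stop("circulation params must have %d entries", NCPAR);
  NumericVector v = clone(volumes);
  double Q[6], P[4]; int va[4];
  circ_step_core(REAL(v), REAL(cpars), P_lv, P_rv, dt, Q, P, va);
  for (int i = 0; i < NVOL; ++i)
    if (v[i] < 0) stop("negative compartment volume (index %d)", i + 1);
  return List::create(
      _["volumes"] = v,
      _["flows"] = NumericVector::create(_["Q_av"] = Q[0], _["Q_sys"] = Q[1],
                                         _["Q_tv"] = Q[2], _["Q_puv"] = Q[3],
                                         _["Q_pul"] = Q[4], _["Q_mv"] = Q[5]),
      _["pressures"] = NumericVector::create(_["P_sa"] = P[0], _["P_sv"] = P[1],
                                             _["P_pa"] = P[2], _["P_pv"] = P[3]),
      _["valves"] = IntegerVector::create(_["av"] = va[0], _["mv"] = va[1],
                                          _["tv"] = va[2], _["pv"] = va[3]));
}

// [[Rcpp::export]]
double vent_pressure_cpp(double V, double Tbar, NumericVector vpars) {
  if (vpars.size() != NVPAR) stop("ventricle params must have %d entries", NVPAR);
  return vent_pressure(V, Tbar, REAL(vpars));
}

// Full coupled run.
// eat: within-cycle activation time (ms) per ensemble node; region: 0/1/2;
// templates: (CL/dt) x 3 matrix of Ca_i (uM) per region over one cycle;
// sl_mode: 0 = fixed SL, 1 = volume-coupled SL = SL_ref*(V/Vref_sl)^(1/3).
// [[Rcpp::export]]
List circ_run_cpp(NumericVector eat, IntegerVector region,
                  NumericMatrix templates, NumericVector mpars,
                  NumericVector mstate0, NumericVector cpars,
                  NumericVector lvpars, NumericVector rvpars,
                  NumericVector vol0, double dt, double cl, int n_cycles,
                  int sl_mode, double sl_fixed, double sl_ref,
                  double vref_sl_lv, double vref_sl_rv, int out_stride) {
  int K = eat.size();
  if (region.size() != K) stop("region/eat length mismatch");
  int nt = templates.nrow();
  if ((int)std::llround(cl / dt) != nt)
    stop("template length (%d) must equal cl/dt (%g)", nt, cl / dt);

  const double* mp = REAL(mpars);
  const double* cp = REAL(cpars);
  double slmin = mp[R_SLmin] + 0.02, slmax = mp[R_SLmax] - 0.02;

  // two myofilament instances per ensemble node: LV bank then RV bank
  std::vector<double> my((size_t)2 * K * NRST);
  for (int k = 0; k < 2 * K; ++k)
    for (int q = 0; q < NRST; ++q) my[(size_t)k * NRST + q] = mstate0[q];

  std::vector<double> vol(REAL(vol0), REAL(vol0) + NVOL);
  double vtot0 = 0.0;
  for (int i = 0; i < NVOL; ++i) vtot0 += vol[i];

  long nsteps = (long)std::llround(n_cycles * cl / dt);
  int nsamp = (int)((nsteps - 1) / out_stride) + 1;
  const int NCOL = 16;
  NumericMatrix trace(nsamp, NCOL);
  long last_start = (long)std::llround((n_cycles - 1) * cl / dt);
  int nlast = (int)(nsteps - last_start);
  NumericMatrix last(nlast, NCOL);

  NumericVector edv(n_cycles), esv(n_cycles);
  for (int c = 0; c < n_cycles; ++c) { edv[c] = -1e30; esv[c] = 1e30; }

  double sl_lv_prev = sl_fixed, sl_rv_prev = sl_fixed;
  if (sl_mode == 1) {
    sl_lv_prev = std::min(std::max(sl_ref * std::cbrt(vol[W_lv] / vref_sl_lv), slmin), slmax);
    sl_rv_prev = std::min(std::max(sl_ref * std::cbrt(vol[W_rv] / vref_sl_rv), slmin), slmax);
  }
  double cons_err = 0.0;
  int neg_vol = 0, k_out = 0, k_last = 0;

  for (long st = 0; st < nsteps; ++st) {
    double t = st * dt;
    int cyc = (int)(t / cl);
    if (cyc >= n_cycles) cyc = n_cycles - 1;

    double sl_lv = sl_fixed, sl_rv = sl_fixed, dsl_lv = 0.0, dsl_rv = 0.0;
    if (sl_mode == 1) {
      sl_lv = std::min(std::max(sl_ref * std::cbrt(vol[W_lv] / vref_sl_lv), slmin), slmax);
      sl_rv = std::min(std::max(sl_ref * std::cbrt(vol[W_rv] / vref_sl_rv), slmin), slmax);
      dsl_lv = (sl_lv - sl_lv_prev) / dt;
      dsl_rv = (sl_rv - sl_rv_prev) / dt;
      sl_lv_prev = sl_lv; sl_rv_prev = sl_rv;
    }

    double tsum_lv = 0.0, tsum_rv = 0.0, atp_lv = 0.0;
    for (int k = 0; k < 2 * K; ++k) {
      int node = k % K;
      bool lv = k < K;
      double ca;
      if (t < eat[node]) {
        ca = templates(0, region[node]);
      } else {
        double ph = pos_fmod(t - eat[node], cl);
        int idx = (int)(ph / dt);
        if (idx >= nt) idx = nt - 1;
        ca = templates(idx, region[node]);
      }
      double SL = lv ? sl_lv : sl_rv;
      double dSL = lv ? dsl_lv : dsl_rv;
      double* y = &my[(size_t)k * NRST];
      double gxbT = rice_step_core(y, mp, ca, SL, dSL, dt);
      double tn = rice_tension(y, mp, SL);
      if (lv) {
        tsum_lv += tn;
        atp_lv += gxbT * sovf(SL, mp).thick * y[M_PostR];
      } else {
        tsum_rv += tn;
      }
    }
    double Tlv = std::max(tsum_lv / K, 0.0);
    double Trv = std::max(tsum_rv / K, 0.0);

    double Plv = vent_pressure(vol[W_lv], Tlv, REAL(lvpars));
    double Prv = vent_pressure(vol[W_rv], Trv, REAL(rvpars));

    if (vol[W_lv] > edv[cyc]) edv[cyc] = vol[W_lv];
    if (vol[W_lv] < esv[cyc]) esv[cyc] = vol[W_lv];

    double Q[6], P[4]; int va[4];
    // record state at time t (before the volume update)
    double Psa = (vol[W_sa] - cp[C_V0sa]) / cp[C_Csa];
    double Psv = (vol[W_sv] - cp[C_V0sv]) / cp[C_Csv];
    double Ppa = (vol[W_pa] - cp[C_V0pa]) / cp[C_Cpa];
    double Ppv = (vol[W_pv] - cp[C_V0pv]) / cp[C_Cpv];
    if (st % out_stride == 0 && k_out < nsamp) {
      double row[NCOL] = {t, Plv, vol[W_lv], Prv, vol[W_rv], Psa, Psv, Ppa, Ppv,
                          Tlv, atp_lv, (double)(Plv > Psa), (double)(Ppv > Plv),
                          (double)(Psv > Prv), (double)(Prv > Ppa), sl_lv};
      for (int c2 = 0; c2 < NCOL; ++c2) trace(k_out, c2) = row[c2];
      ++k_out;
    }
    if (st >= last_start && k_last < nlast) {
      double row[NCOL] = {t, Plv, vol[W_lv], Prv, vol[W_rv], Psa, Psv, Ppa, Ppv,
                          Tlv, atp_lv, (double)(Plv > Psa), (double)(Ppv > Plv),
                          (double)(Psv > Prv), (double)(Prv > Ppa), sl_lv};
      for (int c2 = 0; c2 < NCOL; ++c2) last(k_last, c2) = row[c2];
      ++k_last;
    }

    circ_step_core(vol.data(), cp, Plv, Prv, dt, Q, P, va);
    double vt = 0.0;
    for (int i = 0; i < NVOL; ++i) {
      vt += vol[i];
      if (vol[i] < 0.0) neg_vol = i + 1;
    }
    cons_err = std::max(cons_err, std::fabs(vt - vtot0));
    if (neg_vol) break;
  }

  NumericVector volfin(NVOL);
  for (int i = 0; i < NVOL; ++i) volfin[i] = vol[i];
  return List::create(
      _["trace"] = trace, _["last_cycle"] = last,
      _["edv"] = edv, _["esv"] = esv,
      _["volumes_final"] = volfin,
      _["conservation_err"] = cons_err / std::max(vtot0, 1.0),
      _["negative_volume"] = neg_vol);
}
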