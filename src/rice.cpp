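// R-facing wrappers for the myofilament core (see rice_core.h).

#include <Rcpp.h>
#include <vector>
#include "rice_core.h"
using namespace Rcpp;

// [[Rcpp::export]]
List rice_step_cpp(NumericVector state, NumericVector params, double Ca_uM,
                   double SL, double dSLdt, double dt) {
  if (state.size() != NRST) stop("state must have %d entries", NRST);
  if (params.size() != NRPAR) stop("params must have %d entries", NRPAR);
  if (SL < params[R_SLmin] || SL > params[R_SLmax])
    stop("SL = %g um outside admissible range [%g, %g]", SL,
         params[R_SLmin], params[R_SLmax]);
  NumericVector y = clone(state);
  double gxbT = rice_step_core(REAL(y), REAL(params), Ca_uM, SL, dSLdt, dt);
  Overlap o = sovf(SL, REAL(params));
  return List::create(_["state"] = y, _["g_xbT"] = gxbT,
                      _["SOVF_thick"] = o.thick, _["SOVF_thin"] = o.thin,
                      _["tension"] = rice_tension(REAL(y), REAL(params), SL));
}

// Run one myofilament instance over a sampled Ca drive (uM) at fixed dt (ms).
// SL may be a single value or one value per sample.
// [[Rcpp::export]]
List rice_run_cpp(NumericVector state0, NumericVector params,
                  NumericVector ca_drive, NumericVector sl_drive, double dt,
                  int sample_every) {
  int nt = ca_drive.size();
  bool sl_vec = sl_drive.size() > 1;
  if (sl_vec && sl_drive.size() != nt) stop("sl_drive length mismatch");
  std::vector<double> y(REAL(state0), REAL(state0) + NRST);
  int nout = (nt - 1) / sample_every + 1;
  NumericVector tension(nout), atp(nout), gxb_out(nout), tt(nout);
  NumericMatrix states(NRST, nout);
  double pool_err = 0.0;
  double slprev = sl_drive[0];
  int k = 0;
  for (int i = 0; i < nt; ++i) {
    double SL = sl_vec ? sl_drive[i] : sl_drive[0];
    double dSLdt = (i > 0) ? (SL - slprev) / dt : 0.0;
    slprev = SL;
    double gxbT = rice_step_core(y.data(), REAL(params), ca_drive[i], SL, dSLdt, dt);
    double s = y[M_N] + y[M_P] + y[M_PreR] + y[M_PostR];
    pool_err = std::max(pool_err, std::fabs(s - 1.0));
    if (i % sample_every == 0 && k < nout) {
      tt[k] = i * dt;
      Overlap o = sovf(SL, REAL(params));
      tension[k] = rice_tension(y.data(), REAL(params), SL);
      atp[k] = gxbT * o.thick * y[M_PostR];
      gxb_out[k] = gxbT;
      for (int q = 0; q < NRST; ++q) states(q, k) = y[q];
      ++k;
    }
  }
  NumericVector yfin(NRST);
  for (int q = 0; q < NRST; ++q) yfin[q] = y[q];
  return List::create(_["time"] = tt, _["tension"] = tension, _["atp"] = atp,
                      _["g_xbT"] = gxb_out, _["states"] = states,
                      _["final_state"] = yfin, _["pool_err"] = pool_err);
}
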