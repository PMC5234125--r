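# Single-myocyte electrophysiology: membrane equation, the 12-current set,
# and calcium cycling including the SR balance, with endo/mid/epi variants.

# State vector layout; kept in step with the C++ kernel.
tp06_state_names <- c(
  "V", "m", "h", "j", "xr1", "xr2", "xs", "r", "s", "d", "f", "f2",
  "fcass", "RR", "Ca_i", "Ca_SR", "Ca_SS", "Na_i", "K_i"
)

# Parameter vector layout; kept in step with the C++ kernel.
tp06_param_names <- c(
  "Cm", "G_Na", "G_K1", "G_to", "G_Kr", "G_Ks", "G_CaL", "k_NaCa", "P_NaK",
  "G_pCa", "G_pK", "G_bCa", "G_bNa",
  "V_maxup", "V_rel", "V_leak", "V_xfer",
  "K_o", "Ca_o", "Na_o", "Vc", "Vsr", "Vss",
  "Buf_c", "K_bufc", "Buf_sr", "K_bufsr", "Buf_ss", "K_bufss",
  "k1_prime", "k2_prime", "k3", "k4", "EC", "max_sr", "min_sr",
  "K_up", "K_pCa", "K_mK", "K_mNa", "K_mNai", "K_mCa", "k_sat", "n_NaCa",
  "pK_Na"
)

membrane_current_names <- c(
  "I_Na", "I_K1", "I_to", "I_Kr", "I_Ks", "I_CaL", "I_NaCa", "I_NaK",
  "I_pCa", "I_pK", "I_bCa", "I_bNa"
)

region_code <- function(region) {
  match(match.arg(region, c("endo", "mid", "epi")),
        c("endo", "mid", "epi")) - 1L
}

#' Ventricular cell parameters with transmural variants
#'
#' Constants of the human ventricular ionic model (2006 parameterization)
#' for one of the three transmural cell types. The mid-myocardial variant
#' has a reduced slow delayed-rectifier conductance (`G_Ks`), the
#' endocardial variant a reduced transient-outward conductance (`G_to`)
#' and slower `s`-gate kinetics; these differences produce the transmural
#' APD ordering (mid longest).
#'
#' @param region one of `"endo"`, `"mid"`, `"epi"`.
#' @param overrides named list of constants to override; unknown names are
#'   rejected. Units: conductances nS/pF (or model-native), volumes in the
#'   model's native units, concentrations mM, `Cm` in uF/cm^2.
#' @return an object of class `cell_params`.
#' @export
cell_params <- function(region = c("epi", "endo", "mid"), overrides = list()) {
  region <- match.arg(region)
  p <- c(
    Cm = 2.0, G_Na = 14.838, G_K1 = 5.405,
    G_to = if (region == "endo") 0.073 else 0.294,
    G_Kr = 0.153,
    G_Ks = if (region == "mid") 0.098 else 0.392,
    G_CaL = 3.98e-5, k_NaCa = 1000, P_NaK = 2.724,
    G_pCa = 0.1238, G_pK = 0.0146, G_bCa = 0.000592, G_bNa = 0.00029,
    V_maxup = 0.006375, V_rel = 0.102, V_leak = 0.00036, V_xfer = 0.0038,
    K_o = 5.4, Ca_o = 2.0, Na_o = 140,
    Vc = 0.016404, Vsr = 0.001094, Vss = 5.468e-5,
    Buf_c = 0.2, K_bufc = 0.001, Buf_sr = 10, K_bufsr = 0.3,
    Buf_ss = 0.4, K_bufss = 0.00025,
    k1_prime = 0.15, k2_prime = 0.045, k3 = 0.06, k4 = 0.005,
    EC = 1.5, max_sr = 2.5, min_sr = 1,
    K_up = 0.00025, K_pCa = 0.0005, K_mK = 1, K_mNa = 40,
    K_mNai = 87.5, K_mCa = 1.38, k_sat = 0.1, n_NaCa = 0.35, pK_Na = 0.03
  )
  stopifnot(identical(names(p), tp06_param_names))
  if (length(overrides)) {
    bad <- setdiff(names(overrides), tp06_param_names)
    if (length(bad)) stop("unknown cell parameter(s): ", paste(bad, collapse = ", "))
    p[names(overrides)] <- unlist(overrides)
  }
  if (p[["Cm"]] <= 0) stop("Cm must be positive")
  if (p[["Vc"]] <= 0 || p[["Vsr"]] <= 0) stop("cell volumes must be positive")
  cond <- c("G_Na", "G_K1", "G_to", "G_Kr", "G_Ks", "G_CaL", "k_NaCa",
            "P_NaK", "G_pCa", "G_pK", "G_bCa", "G_bNa")
  if (any(p[cond] < 0)) stop("conductances must be non-negative")
  structure(list(region = region, values = p), class = "cell_params")
}

#' Resting cell state
#'
#' The published resting initial condition of the ionic model: membrane
#' potential, gating variables and intracellular/SR concentrations.
#'
#' @param overrides named list of state entries to override.
#' @return an object of class `cell_state` (named numeric vector).
#' @export
cell_state <- function(overrides = list()) {
  y <- c(V = -86.2, m = 0, h = 0.75, j = 0.75, xr1 = 0, xr2 = 1, xs = 0,
         r = 0, s = 1, d = 0, f = 1, f2 = 1, fcass = 1, RR = 1,
         Ca_i = 0.00007, Ca_SR = 1.3, Ca_SS = 0.00007,
         Na_i = 7.67, K_i = 138.3)
  stopifnot(identical(names(y), tp06_state_names))
  if (length(overrides)) {
    bad <- setdiff(names(overrides), tp06_state_names)
    if (length(bad)) stop("unknown state entries: ", paste(bad, collapse = ", "))
    y[names(overrides)] <- unlist(overrides)
  }
  validate_cell_state(y)
  structure(y, class = "cell_state")
}

validate_cell_state <- function(y) {
  if (!all(is.finite(y))) {
    stop("non-finite cell state in field(s): ",
         paste(tp06_state_names[!is.finite(y)], collapse = ", "))
  }
  gates <- tp06_state_names[2:14]
  bad <- gates[y[gates] < 0 | y[gates] > 1]
  if (length(bad)) stop("gating variable(s) outside [0,1]: ", paste(bad, collapse = ", "))
  conc <- c("Ca_i", "Ca_SR", "Ca_SS", "Na_i", "K_i")
  bad <- conc[y[conc] <= 0]
  if (length(bad)) stop("non-positive concentration(s): ", paste(bad, collapse = ", "))
  invisible(y)
}

#' Membrane currents and SR fluxes at a given state
#'
#' Evaluates the twelve membrane currents (in pA/pF) and the three SR
#' calcium fluxes (plus the subspace transfer flux) at the supplied state.
#'
#' @param state a [cell_state()].
#' @param params a [cell_params()].
#' @return named numeric vector with the 12 membrane currents
#'   (`I_Na` ... `I_bNa`), then `I_leak`, `I_up`, `I_rel`, `I_xfer`.
#' @export
ionic_currents <- function(state, params) {
  validate_cell_state(unclass(state))
  tp06_currents_cpp(as.numeric(state), as.numeric(params$values),
                    region_code(params$region))
}

#' Total transmembrane ionic current
#'
#' Sum of exactly the twelve membrane currents; SR fluxes are excluded.
#'
#' @param currents output of [ionic_currents()] (or any named vector
#'   containing the twelve membrane-current entries).
#' @return scalar total current (pA/pF).
#' @export
total_ionic_current <- function(currents) {
  if (!all(membrane_current_names %in% names(currents)))
    stop("currents must contain the 12 membrane-current fields")
  sum(currents[membrane_current_names])
}

#' Advance a single cell by one time step
#'
#' Gates are advanced with a Rush-Larsen exponential integrator (so they
#' remain in \[0,1\] by construction), concentrations by forward updates
#' with analytic buffering, and the membrane potential by
#' dV/dt = -(I_ion + I_stim).
#'
#' @param state a [cell_state()].
#' @param params a [cell_params()].
#' @param I_stim stimulus current (pA/pF; negative depolarizes).
#' @param dt time step (ms).
#' @param max_dt enforced stability limit (ms).
#' @return list with the new `state` and the total ionic current `I_ion`.
#' @export
step_cell <- function(state, params, I_stim = 0, dt = 0.02, max_dt = 0.05) {
  if (dt <= 0 || dt > max_dt)
    stop(sprintf("dt = %g ms outside (0, %g]", dt, max_dt))
  validate_cell_state(unclass(state))
  out <- tp06_step_cpp(as.numeric(state), as.numeric(params$values),
                       region_code(params$region), I_stim, dt)
  names(out$state) <- tp06_state_names
  out$state <- structure(out$state, class = "cell_state")
  out
}

#' Pacing protocol
#'
#' @param cl cycle length (ms).
#' @param amplitude stimulus amplitude (pA/pF; negative depolarizes).
#' @param duration stimulus duration (ms).
#' @param onset within-cycle stimulus onset (ms).
#' @param n_beats number of paced beats.
#' @return object of class `stimulus_protocol`.
#' @export
stimulus_protocol <- function(cl = 600, amplitude = -52, duration = 1,
                              onset = 0, n_beats = 1) {
  if (!(cl > duration && duration > 0))
    stop("require cycle length > stimulus duration > 0")
  if (n_beats < 1) stop("n_beats must be >= 1")
  structure(list(cl = cl, amplitude = amplitude, duration = duration,
                 onset = onset, n_beats = n_beats),
            class = "stimulus_protocol")
}

#' Run a paced single-cell simulation
#'
#' @param params a [cell_params()].
#' @param protocol a [stimulus_protocol()].
#' @param dt integration step (ms); default 0.02.
#' @param sample_every store every this-many steps.
#' @param record_currents also store the per-sample current set.
#' @param init initial [cell_state()]; defaults to the published rest state.
#' @return object of class `cell_trace`: list with `time` (ms), `V` (mV),
#'   `Ca_i` (mM), optional `currents` (16 x n), `final_state`, the protocol,
#'   and integrator diagnostics (`gate_min`, `gate_max`, `conc_min`).
#' @export
run_paced_cell <- function(params, protocol, dt = 0.02, sample_every = 50L,
                           record_currents = FALSE, init = cell_state()) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  out <- tp06_run_cell_cpp(as.numeric(init), as.numeric(params$values),
                           region_code(params$region),
                           protocol$cl, protocol$amplitude, protocol$duration,
                           protocol$onset, protocol$n_beats, dt,
                           as.integer(sample_every), record_currents)
  if (out$blowup_beat > 0)
    stop("numerical blow-up (|V| > 200 mV) during beat ", out$blowup_beat)
  names(out$final_state) <- tp06_state_names
  if (record_currents)
    rownames(out$currents) <- c(membrane_current_names,
                                "I_leak", "I_up", "I_rel", "I_xfer")
  out$protocol <- protocol
  out$dt <- dt
  class(out) <- "cell_trace"
  out
}

#' Action-potential and calcium-transient metrics of the final beat
#'
#' APD90 is measured from the upstroke (maximum dV/dt) to 90%
#' repolarization. When no action potential is detected (amplitude below
#' `min_amplitude`), metrics are returned as `NA` with `ap_detected =
#' FALSE`, never as zero.
#'
#' @param trace a `cell_trace` from [run_paced_cell()], or a list with
#'   `time`, `V` and optionally `Ca_i` covering at least one beat.
#' @param cl cycle length (ms); taken from the trace protocol when present.
#' @param min_amplitude minimal AP amplitude (mV) to count as an AP.
#' @return list: `ap_detected`, `V_rest`, `V_peak`, `APD90` (ms),
#'   `Ca_amplitude` (mM), `Ca_time_to_peak` (ms).
#' @export
ap_metrics <- function(trace, cl = NULL, min_amplitude = 30) {
  if (is.null(cl)) cl <- trace$protocol$cl
  if (is.null(cl)) stop("cycle length not supplied and absent from trace")
  t <- trace$time
  if (max(t) < cl) stop("trace must contain at least one full beat")
  n_beats <- floor(max(t) / cl + 1e-9)
  w <- t >= (n_beats - 1) * cl & t <= n_beats * cl
  tw <- t[w]; Vw <- trace$V[w]
  V_rest <- min(Vw); V_peak <- max(Vw)
  none <- list(ap_detected = FALSE, V_rest = V_rest, V_peak = V_peak,
               APD90 = NA_real_, Ca_amplitude = NA_real_,
               Ca_time_to_peak = NA_real_)
  if (V_peak - V_rest < min_amplitude) return(none)
  dv <- diff(Vw)
  i_up <- which.max(dv)
  t_up <- tw[i_up]
  i_peak <- which.max(Vw)
  V90 <- V_peak - 0.9 * (V_peak - V_rest)
  below <- which(Vw[-1] <= V90 & seq_along(Vw[-1]) >= i_peak)
  if (!length(below)) return(none)
  i2 <- below[1] + 1L
  # linear interpolation of the downward crossing
  t90 <- tw[i2 - 1] + (tw[i2] - tw[i2 - 1]) *
    (Vw[i2 - 1] - V90) / (Vw[i2 - 1] - Vw[i2])
  ca_amp <- NA_real_; ca_ttp <- NA_real_
  if (!is.null(trace$Ca_i)) {
    Cw <- trace$Ca_i[w]
    ca_amp <- max(Cw) - min(Cw)
    ca_ttp <- tw[which.max(Cw)] - t_up
  }
  list(ap_detected = TRUE, V_rest = V_rest, V_peak = V_peak,
       APD90 = t90 - t_up, Ca_amplitude = ca_amp, Ca_time_to_peak = ca_ttp)
}

#' Write a cell trace as CSV
#'
#' Columns: `time_ms`, `V_mV`, `Ca_i_mM`, plus one column per current when
#' the trace recorded them.
#'
#' @param trace a `cell_trace`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_cell_trace <- function(trace, path) {
  df <- data.frame(time_ms = trace$time, V_mV = trace$V, Ca_i_mM = trace$Ca_i)
  if (!is.null(trace$currents) && nrow(trace$currents) > 0)
    df <- cbind(df, as.data.frame(t(trace$currents)))
  write_atomic_csv(df, path)
}
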