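# Lumped hemodynamics: a thin-wall ventricle surrogate for each ventricle,
# two series Windkessel compartments per circulation (systemic and
# pulmonic), ideal-diode valves, and the 10%-compliance failing preset.

circ_param_names <- c(
  "R_av", "R_sys", "R_tv", "R_puv", "R_pul", "R_mv",
  "C_sa", "C_sv", "C_pa", "C_pv",
  "V0_sa", "V0_sv", "V0_pa", "V0_pv"
)

vent_param_names <- c("B", "kappa", "V_rest", "alpha", "V_ref")

#' Circulation parameters
#'
#' Resistances (mmHg s/mL), compliances (mL/mmHg) and unstressed volumes
#' (mL) of the four Windkessel compartments (systemic arterial+capillary,
#' systemic venous, pulmonic arterial+capillary, pulmonic venous) and the
#' four valve resistances. Defaults are tuned once so that the 70 cm/s
#' baseline with the failing preset operates near end-diastolic volume
#' ~88-90 mL and systolic LV pressure ~140-150 mmHg (see the tuning script
#' in `scripts/`).
#'
#' @param failing apply the failing-ventricle preset (all vascular
#'   compliances reduced by 10%) at construction.
#' @param overrides named list of parameter overrides (applied before the
#'   failing preset).
#' @return object of class `circulation_params` (named numeric vector with
#'   attribute `failing`).
#' @export
circulation_params <- function(failing = FALSE, overrides = list()) {
  p <- c(R_av = 0.02, R_sys = 2.55, R_tv = 0.015, R_puv = 0.02,
         R_pul = 0.10, R_mv = 0.02,
         C_sa = 6, C_sv = 30, C_pa = 4, C_pv = 9,
         V0_sa = 320, V0_sv = 2200, V0_pa = 90, V0_pv = 90)
  stopifnot(identical(names(p), circ_param_names))
  if (length(overrides)) {
    bad <- setdiff(names(overrides), circ_param_names)
    if (length(bad)) stop("unknown circulation parameter(s): ",
                          paste(bad, collapse = ", "))
    p[names(overrides)] <- unlist(overrides)
  }
  if (any(p[1:10] <= 0)) stop("resistances and compliances must be positive")
  out <- structure(p, class = "circulation_params", failing = FALSE)
  if (failing) out <- apply_failing_condition(out)
  out
}

#' Failing-ventricle preset: stiffened vasculature
#'
#' Multiplies every vascular compliance by 0.9 (mimicking atherosclerotic/
#' hypertensive stiffening); resistances and unstressed volumes are
#' unchanged. Guarded: re-applying to an already-failing parameter set is
#' an error.
#'
#' @param params a [circulation_params()].
#' @return the modified parameters with `failing = TRUE`.
#' @export
apply_failing_condition <- function(params) {
  stopifnot(inherits(params, "circulation_params"))
  if (isTRUE(attr(params, "failing")))
    stop("failing preset already applied")
  params[c("C_sa", "C_sv", "C_pa", "C_pv")] <-
    0.9 * params[c("C_sa", "C_sv", "C_pa", "C_pv")]
  attr(params, "failing") <- TRUE
  params
}

#' Ventricle surrogate parameters
#'
#' Thin-wall lumped stand-in for the finite-element ventricle: exponential
#' passive pressure `B (exp(kappa (V - V_rest)) - 1)` plus an active term
#' `alpha * T * (V/V_ref)^(-2/3)` (Laplace scaling of wall tension to
#' cavity pressure).
#'
#' @param which `"lv"` or `"rv"`.
#' @param overrides named list of overrides.
#' @return object of class `ventricle_params` (named numeric vector).
#' @export
ventricle_params <- function(which = c("lv", "rv"), overrides = list()) {
  which <- match.arg(which)
  p <- if (which == "lv") {
    c(B = 0.25, kappa = 0.10, V_rest = 48, alpha = 450, V_ref = 100)
  } else {
    c(B = 0.12, kappa = 0.08, V_rest = 48, alpha = 117, V_ref = 100)
  }
  stopifnot(identical(names(p), vent_param_names))
  if (length(overrides)) {
    bad <- setdiff(names(overrides), vent_param_names)
    if (length(bad)) stop("unknown ventricle parameter(s): ",
                          paste(bad, collapse = ", "))
    p[names(overrides)] <- unlist(overrides)
  }
  structure(p, class = "ventricle_params", which = which)
}

#' Ventricular pressure from volume and ensemble tension
#'
#' @param vent a [ventricle_params()].
#' @param tension normalized ensemble active tension (clamped at 0).
#' @param V cavity volume (mL), > 0.
#' @return pressure (mmHg).
#' @export
ventricle_pressure <- function(vent, tension, V) {
  if (any(V <= 0)) stop("cavity volume must be positive")
  vapply(seq_along(V), function(i)
    vent_pressure_cpp(V[i], tension[min(i, length(tension))],
                      as.numeric(vent)), numeric(1))
}

#' Initial hemodynamic state (compartment volumes)
#'
#' @param params a [circulation_params()].
#' @param P named starting pressures (mmHg) for sa/sv/pa/pv.
#' @param V_lv,V_rv starting ventricular volumes (mL).
#' @return named volume vector (mL): `V_lv`, `V_rv`, `V_sa`, `V_sv`,
#'   `V_pa`, `V_pv`.
#' @export
hemo_state_init <- function(params = circulation_params(),
                            P = c(sa = 120, sv = 9, pa = 14, pv = 11),
                            V_lv = 110, V_rv = 110) {
  c(V_lv = V_lv, V_rv = V_rv,
    V_sa = params[["V0_sa"]] + params[["C_sa"]] * P[["sa"]],
    V_sv = params[["V0_sv"]] + params[["C_sv"]] * P[["sv"]],
    V_pa = params[["V0_pa"]] + params[["C_pa"]] * P[["pa"]],
    V_pv = params[["V0_pv"]] + params[["C_pv"]] * P[["pv"]])
}

#' One circulation step
#'
#' Flows Q = dP/R gated by ideal-diode valves; compartment volumes update
#' by inflow minus outflow (conserving total blood volume exactly);
#' compartment pressures follow the linear PV relation P = (V - V0)/C.
#'
#' @param volumes named length-6 volume vector (see [hemo_state_init()]).
#' @param params a [circulation_params()].
#' @param P_lv,P_rv current ventricular pressures (mmHg).
#' @param dt step (ms).
#' @return list: `volumes`, `flows` (mL/s), `pressures` (mmHg), `valves`.
#' @export
step_circulation <- function(volumes, params, P_lv, P_rv, dt = 0.1) {
  if (dt <= 0) stop("dt must be positive")
  out <- circ_step_cpp(as.numeric(volumes), as.numeric(params),
                       P_lv, P_rv, dt)
  names(out$volumes) <- names(volumes)
  out
}

#' Run the coupled mechanics-circulation simulation
#'
#' Drives an ensemble of myofilament instances (one per activation-map
#' sample, subsampled by stratified activation-time quantiles) through
#' `n_cycles` cardiac cycles. Each instance receives its region's calcium
#' template shifted by its activation time; the ensemble-mean tension sets
#' ventricular pressure through the thin-wall surrogate. With
#' `sl_coupling` (the default) sarcomere length follows cavity volume as
#' `SL_ref (V / V_ref_sl)^(1/3)`, which is how activation dispersion
#' reaches the energetic readouts.
#'
#' @param eat_map an `eat_map` (nodes with `NA` are excluded and noted).
#' @param geom the `tissue_geometry` the map came from (for region labels);
#'   optional if the map rows align with `regions`.
#' @param n_cycles number of cycles (default 32).
#' @param config a configuration list as produced by [default_config()]
#'   (blocks `circulation` and `myofilament` are used).
#' @param templates optional named list of `ca_template`s per region;
#'   computed (and cached per session) when missing.
#' @return object of class `hemo_trace`: list with `trace` (data.frame at
#'   the output stride), `last_cycle` (full resolution), `edv`, `esv` per
#'   cycle, `conservation_err`, `ensemble` (node, eat, region), and the
#'   parameter objects used.
#' @export
run_cardiac_cycles <- function(eat_map, geom = NULL, n_cycles = 32,
                               config = default_config(),
                               templates = NULL) {
  cc <- config$circulation
  mf <- config$myofilament
  cl <- config$sweep$cl
  dt <- cc$dt
  ok <- !is.na(eat_map$eat_ms)
  if (!any(ok)) stop("activation map has no activated nodes")
  if (any(!ok))
    message(sum(!ok), " node(s) without activation excluded from mechanics")
  nodes <- eat_map$node[ok]
  eat <- eat_map$eat_ms[ok]
  regions <- if (!is.null(geom)) geom$nodes$region[nodes]
             else rep("epi", length(nodes))
  # condition-independent ensemble: stratified over region and spatial
  # position (raster order), so the same myocardial sample is compared
  # across conduction-velocity conditions and only its activation times
  # change
  K <- min(cc$ensemble_size, length(eat))
  idx <- seq_along(nodes)
  pick <- integer(0)
  for (r in c("endo", "mid", "epi")) {
    ir <- idx[regions == r]
    kr <- round(K * length(ir) / length(idx))
    if (length(ir) && kr > 0)
      pick <- c(pick, ir[unique(round(seq(1, length(ir), length.out = kr)))])
  }
  if (!length(pick)) pick <- idx[unique(round(seq(1, length(idx), length.out = K)))]
  eat_s <- eat[pick]; reg_s <- regions[pick]
  reg_code <- match(reg_s, c("endo", "mid", "epi")) - 1L

  if (is.null(templates)) templates <- ca_template_set(cl, mf$template_dt)
  nt <- as.integer(round(cl / dt))
  tmpl <- vapply(c("endo", "mid", "epi"), function(r) {
    tm <- templates[[r]]
    approx(tm$time, tm$ca * 1000, xout = (seq_len(nt) - 1) * dt, rule = 2)$y
  }, numeric(nt))

  mp <- myofilament_params(mf$overrides)
  cp <- circulation_params(failing = cc$failing, overrides = cc$overrides)
  lv <- ventricle_params("lv", cc$lv)
  rv <- ventricle_params("rv", cc$rv)
  ip <- cc$init_pressures
  vol0 <- hemo_state_init(cp, P = c(sa = ip$sa, sv = ip$sv, pa = ip$pa,
                                    pv = ip$pv))

  out <- circ_run_cpp(eat_s, reg_code, tmpl, as.numeric(mp),
                      as.numeric(myo_state(mp)), as.numeric(cp),
                      as.numeric(lv), as.numeric(rv), as.numeric(vol0),
                      dt, cl, as.integer(n_cycles),
                      as.integer(cc$sl_coupling), mf$sl_default,
                      cc$sl_ref, cc$v_ref_sl_lv, cc$v_ref_sl_rv,
                      as.integer(cc$out_stride))
  if (out$negative_volume > 0)
    stop("negative compartment volume (compartment ", out$negative_volume, ")")
  cols <- c("time_ms", "P_lv", "V_lv", "P_rv", "V_rv", "P_sa", "P_sv",
            "P_pa", "P_pv", "tension_lv", "atp_lv",
            "valve_av", "valve_mv", "valve_tv", "valve_pv", "SL_lv")
  trace <- as.data.frame(out$trace); names(trace) <- cols
  last <- as.data.frame(out$last_cycle); names(last) <- cols
  res <- structure(list(trace = trace, last_cycle = last,
                        edv = out$edv, esv = out$esv,
                        conservation_err = out$conservation_err,
                        ensemble = data.frame(node = nodes[pick],
                                              eat_ms = eat_s,
                                              region = reg_s),
                        cl = cl, dt = dt, n_cycles = n_cycles,
                        params = list(circulation = cp, lv = lv, rv = rv,
                                      myofilament = mp)),
                   class = "hemo_trace")
  chk <- steady_state_check(res)
  if (!chk$converged)
    warning(sprintf("cycle-to-cycle EDV drift %.3g%% exceeds 0.1%%",
                    chk$drift))
  res
}

# Session cache of per-region calcium templates.
.template_cache <- new.env(parent = emptyenv())

ca_template_set <- function(cl, sample_dt = 0.1) {
  key <- paste0("cl", cl, "_dt", sample_dt)
  if (is.null(.template_cache[[key]])) {
    .template_cache[[key]] <- lapply(
      stats::setNames(nm = c("endo", "mid", "epi")),
      function(r) make_ca_template(r, cl = cl, sample_dt = sample_dt))
  }
  .template_cache[[key]]
}

#' Steady-state convergence of a cardiac-cycle run
#'
#' Relative end-diastolic-volume drift between the last two cycles;
#' converged when below 0.1%.
#'
#' @param trace a `hemo_trace` (or list with per-cycle `edv`).
#' @return list `converged` (logical), `drift` (percent).
#' @export
steady_state_check <- function(trace) {
  edv <- trace$edv
  if (length(edv) < 3) stop("need at least 3 cycles")
  n <- length(edv)
  drift <- abs(edv[n] - edv[n - 1]) / edv[n - 1] * 100
  list(converged = drift < 0.1, drift = drift)
}

#' Write a hemodynamic trace as CSV
#'
#' @param trace a `hemo_trace`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_hemo_trace <- function(trace, path) {
  write_atomic_csv(trace$trace, path)
}
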