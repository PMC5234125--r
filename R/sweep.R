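# Experiment orchestration: the five-MCV-condition sweep under sinus
# pacing, per-cycle metric extraction, and the monotonic-trend analysis.

#' Pressure-volume metrics of the final cycle
#'
#' EDV and ESV are the extrema of LV volume over the cycle, SV = EDV - ESV
#' and EF = 100 SV / EDV exactly, stroke work is the PV-loop area by
#' trapezoidal quadrature, MAP the time-average systemic arterial
#' pressure, and the ATP consumption the node-summed cycle-average rate.
#'
#' @param hemo a `hemo_trace` from [run_cardiac_cycles()].
#' @return object of class `cycle_metrics` (named list).
#' @export
pv_metrics <- function(hemo) {
  lc <- hemo$last_cycle
  edv <- max(lc$V_lv); esv <- min(lc$V_lv)
  sv <- edv - esv
  ef <- 100 * sv / edv
  sw <- pv_loop_area(lc$P_lv, lc$V_lv)
  tt <- lc$time_ms / 1000
  trap <- function(y) sum(diff(tt) * (y[-1] + y[-length(y)]) / 2) / diff(range(tt))
  metrics <- list(
    eat_duration_ms = NA_real_,
    p_sys_mmhg = max(lc$P_lv),
    map_mmhg = trap(lc$P_sa),
    edv_ml = edv, esv_ml = esv, sv_ml = sv, ef_pct = ef,
    sw_mmhg_ml = sw,
    atp_per_s = trap(lc$atp_lv)
  )
  drift <- abs(lc$V_lv[length(lc$V_lv)] - lc$V_lv[1])
  if (drift > 0.002 * edv) {
    warning(sprintf("PV loop not closed: volume drift %.3g mL over the cycle",
                    drift))
    attr(metrics, "loop_drift_ml") <- drift
  }
  class(metrics) <- "cycle_metrics"
  metrics
}

# Signed area enclosed by the (V, P) loop; positive for the usual
# counter-clockwise ejection loop.
pv_loop_area <- function(P, V) {
  P2 <- c(P, P[1]); V2 <- c(V, V[1])
  abs(sum((P2[-1] + P2[-length(P2)]) / 2 * diff(V2)))
}

#' Pumping-efficiency index: stroke work per cycle ATP consumption
#'
#' @param metrics a `cycle_metrics` (or any list with `sw_mmhg_ml` and
#'   `atp_per_s`).
#' @return SW / ATP (mmHg mL per ATP-rate unit).
#' @export
sw_per_atp <- function(metrics) {
  if (is.na(metrics$atp_per_s) || metrics$atp_per_s <= 0)
    stop("ATP consumption must be positive")
  metrics$sw_mmhg_ml / metrics$atp_per_s
}

#' Run the full conduction-velocity sweep
#'
#' For each target conduction velocity: calibrate cellular resistivity on
#' a cable matched to the fixture spacing, run the tissue electrical
#' simulation under the sinus protocol, extract the final-cycle activation
#' map, run the mechanical cycles, and compute the cycle metrics. The
#' pipeline is deterministic end to end for a fixed configuration.
#'
#' @param conditions target velocities (cm/s), ascending or not.
#' @param config a configuration list (see [default_config()]).
#' @param geom optional `tissue_geometry`; defaults to the reference sweep
#'   shell.
#' @param protocol optional `sinus_protocol`; defaults to the reference
#'   protocol on `geom` seeded from `config$seed`.
#' @param quiet suppress progress messages.
#' @return object of class `sweep_result`: data.frame with one row per
#'   condition (`mcv_cm_s`, `rho_ohm_cm`, the cycle metrics, and
#'   `sw_per_atp`), with excluded conditions recorded in the
#'   `excluded` attribute.
#' @export
run_mcv_sweep <- function(conditions = NULL, config = default_config(),
                          geom = NULL, protocol = NULL, quiet = FALSE) {
  if (is.null(conditions)) conditions <- config$sweep$conditions
  suite <- reference_fixture_suite()
  if (is.null(geom)) geom <- make_geometry(suite$sweep_shell$spec)
  if (is.null(protocol)) {
    pr <- config$fixtures$protocol
    protocol <- make_sinus_protocol(
      geom, n_sites = pr$n_sites, onset = pr$onset,
      purkinje_speed = pr$purkinje_speed, cl = config$sweep$cl,
      stim_delay = pr$stim_delay, seed = config$seed)
  }
  tissue <- config$tissue
  calib_spec <- fixture_spec("cable", dims = 2.0, dx = geom$dx,
                             layer_fractions = c(0, 0, 1))
  calib_geom <- make_geometry(calib_spec)
  tp_template <- tissue_params(rho = tissue$rho, S = tissue$S, Cm = tissue$Cm)
  duration <- config$sweep$electrical_duration
  cl <- config$sweep$cl
  last_cycle <- as.integer(floor((duration - 1e-9) / cl)) + 1L

  rows <- list(); excluded <- list()
  for (mcv in conditions) {
    if (!quiet) message("condition ", mcv, " cm/s: calibrating resistivity")
    cal <- tryCatch(
      calibrate_resistivity(mcv, calib_geom, tp_template,
                            tol = config$sweep$calibration_tol,
                            dt = tissue$dt),
      error = function(e) e)
    if (inherits(cal, "error")) {
      warning("condition ", mcv, " cm/s excluded: ", conditionMessage(cal))
      excluded[[as.character(mcv)]] <- conditionMessage(cal)
      next
    }
    tp <- tissue_params(rho = cal$rho, S = tissue$S, Cm = tissue$Cm)
    if (!quiet)
      message(sprintf("  rho = %.1f Ohm cm (cv %.2f cm/s); electrical run",
                      cal$rho, cal$cv))
    run <- run_tissue_paced(geom, tp, protocol, duration = duration,
                            dt = tissue$dt, threshold = tissue$threshold)
    map <- run$maps[[last_cycle]]
    if (!quiet) message("  mechanics: ", config$sweep$n_cycles, " cycles")
    hemo <- run_cardiac_cycles(map, geom, n_cycles = config$sweep$n_cycles,
                               config = config)
    m <- pv_metrics(hemo)
    m$eat_duration_ms <- eat_duration(map)
    rows[[as.character(mcv)]] <- data.frame(
      mcv_cm_s = mcv, rho_ohm_cm = cal$rho, achieved_cv_cm_s = cal$cv,
      eat_duration_ms = m$eat_duration_ms, eat_min_ms = min(map$eat_ms, na.rm = TRUE),
      p_sys_mmhg = m$p_sys_mmhg, map_mmhg = m$map_mmhg,
      edv_ml = m$edv_ml, esv_ml = m$esv_ml, sv_ml = m$sv_ml,
      ef_pct = m$ef_pct, sw_mmhg_ml = m$sw_mmhg_ml, atp_per_s = m$atp_per_s,
      sw_per_atp = sw_per_atp(m))
  }
  if (!length(rows)) stop("no condition completed")
  out <- do.call(rbind, rows)
  out <- out[order(out$mcv_cm_s), ]
  rownames(out) <- NULL
  structure(out, class = c("sweep_result", "data.frame"),
            excluded = excluded, seed = config$seed)
}

sweep_trend_spec <- function() {
  data.frame(
    metric = c("eat_duration_ms", "edv_ml", "esv_ml", "sv_ml", "ef_pct",
               "p_sys_mmhg", "sw_mmhg_ml", "atp_per_s", "sw_per_atp"),
    expected = c("decreasing", "decreasing", "decreasing", "increasing",
                 "increasing", "increasing", "increasing", "decreasing",
                 "increasing"),
    stringsAsFactors = FALSE)
}

#' Monotonic-trend report across conduction-velocity conditions
#'
#' Direction of each metric across ascending MCV, whether it is strictly
#' monotone, and whether it matches the expected physiological direction
#' (activation duration, volumes and ATP fall with faster conduction;
#' pressure, stroke volume/work, ejection fraction and efficiency rise).
#'
#' @param result a `sweep_result` (>= 2 conditions).
#' @return data.frame: `metric`, `direction`, `strictly_monotone`,
#'   `expected`, `matches_expected`.
#' @export
monotonicity_report <- function(result) {
  if (nrow(result) < 2) stop("need at least 2 conditions")
  result <- result[order(result$mcv_cm_s), ]
  spec <- sweep_trend_spec()
  spec <- spec[spec$metric %in% names(result), ]
  rows <- lapply(seq_len(nrow(spec)), function(i) {
    v <- result[[spec$metric[i]]]
    d <- diff(v)
    dir <- if (all(d > 0)) "increasing" else if (all(d < 0)) "decreasing"
           else if (all(d >= 0)) "non-decreasing" else if (all(d <= 0)) "non-increasing"
           else "none"
    strict <- all(d > 0) || all(d < 0)
    data.frame(metric = spec$metric[i], direction = dir,
               strictly_monotone = strict, expected = spec$expected[i],
               matches_expected = strict && dir == spec$expected[i],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
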