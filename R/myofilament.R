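# Cross-bridge / regulatory-protein myofilament dynamics: active tension
# and contractile ATP consumption, driven by activation-time-shifted
# calcium transients (one-way excitation-contraction coupling).

rice_param_names <- c(
  "kon", "koffL", "koffH", "perm50", "nperm", "knp", "kpn",
  "fapp", "gapp", "gslmod", "hf", "hfmdc", "hb", "gxb", "sigmap", "sigman",
  "x0", "xPsi", "len_thick", "len_hbare", "len_thin", "SLmin", "SLmax"
)

rice_state_names <- c("N_xB", "P_xB", "XB_PreR", "XB_PostR",
                      "TropCaL", "TropCaH", "xXB_PreR", "xXB_PostR")

#' Myofilament model constants
#'
#' Rate constants of the cross-bridge cycle (s^-1; `kon` in uM^-1 s^-1),
#' cooperativity of thin-filament activation, strain-dependence factors,
#' and sarcomere geometry (um). Values follow the cited cross-bridge
#' model's reference parameterization.
#'
#' @param overrides named list of constants to override.
#' @return object of class `myofilament_params` (named numeric vector).
#' @export
myofilament_params <- function(overrides = list()) {
  p <- c(kon = 50, koffL = 250, koffH = 25, perm50 = 0.5, nperm = 15,
         knp = 500, kpn = 50,
         fapp = 500, gapp = 70, gslmod = 6, hf = 2000, hfmdc = 5,
         hb = 400, gxb = 70, sigmap = 8, sigman = 1,
         x0 = 0.007, xPsi = 2,
         len_thick = 1.65, len_hbare = 0.1, len_thin = 1.2,
         SLmin = 1.4, SLmax = 2.4)
  stopifnot(identical(names(p), rice_param_names))
  if (length(overrides)) {
    bad <- setdiff(names(overrides), rice_param_names)
    if (length(bad)) stop("unknown myofilament parameter(s): ",
                          paste(bad, collapse = ", "))
    p[names(overrides)] <- unlist(overrides)
  }
  structure(p, class = "myofilament_params")
}

#' Resting myofilament state
#'
#' Nearly all regulatory units non-permissive, no attached cross-bridges,
#' post-rotation mean strain at the power-stroke size `x0`.
#'
#' @param params a [myofilament_params()] (supplies `x0`).
#' @param overrides named list of state entries to override.
#' @return object of class `myo_state` (named numeric vector).
#' @export
myo_state <- function(params = myofilament_params(), overrides = list()) {
  y <- c(N_xB = 0.99, P_xB = 0.01, XB_PreR = 0, XB_PostR = 0,
         TropCaL = 0.01, TropCaH = 0.01,
         xXB_PreR = 0, xXB_PostR = unname(params[["x0"]]))
  stopifnot(identical(names(y), rice_state_names))
  if (length(overrides)) {
    bad <- setdiff(names(overrides), rice_state_names)
    if (length(bad)) stop("unknown state entries: ", paste(bad, collapse = ", "))
    y[names(overrides)] <- unlist(overrides)
  }
  pool <- sum(y[1:4])
  if (abs(pool - 1) > 1e-8)
    stop("regulatory pool must sum to 1 (got ", format(pool), ")")
  if (any(y[1:6] < 0)) stop("fractions must be non-negative")
  structure(y, class = "myo_state")
}

#' Thick/thin filament single-overlap fractions at a sarcomere length
#'
#' @param SL sarcomere length (um).
#' @param params a [myofilament_params()].
#' @return named vector `thick`, `thin` (each in \[0,1\]).
#' @export
overlap_fractions <- function(SL, params = myofilament_params()) {
  ze <- pmin(params[["len_thick"]] / 2, SL / 2)
  cle <- pmax(SL / 2 - (SL - params[["len_thin"]]), params[["len_hbare"]] / 2)
  lo <- pmax(ze - cle, 0)
  c(thick = lo * 2 / (params[["len_thick"]] - params[["len_hbare"]]),
    thin = lo / params[["len_thin"]])
}

#' Advance the myofilament state by one step
#'
#' The four-state regulatory/cross-bridge pool advances by an exactly
#' conservative explicit update; troponin occupancies and mean strains,
#' linear in their own variable, use exponential updates.
#'
#' @param state a [myo_state()].
#' @param Ca_i intracellular calcium (mM).
#' @param SL sarcomere length (um); must lie in the model's range.
#' @param dt step (ms).
#' @param dSLdt sarcomere shortening velocity (um/ms).
#' @param params a [myofilament_params()].
#' @return list: new `state`, `g_xbT` (s^-1), `SOVF_thick`, `tension`.
#' @export
step_myofilament <- function(state, Ca_i, SL = 2.0, dt = 0.1, dSLdt = 0,
                             params = myofilament_params()) {
  if (Ca_i < 0) stop("Ca_i must be non-negative")
  out <- rice_step_cpp(as.numeric(state), as.numeric(params),
                       Ca_i * 1000, SL, dSLdt, dt)
  names(out$state) <- rice_state_names
  out$state <- structure(out$state, class = "myo_state")
  out
}

# Current cross-bridge detachment rate (s^-1) implied by the state's
# post-rotation mean strain.
gxb_of_state <- function(state, params = myofilament_params()) {
  x0 <- params[["x0"]]; xp <- state[["xXB_PostR"]]
  md <- if (xp < x0) exp(params[["sigmap"]] * ((x0 - xp) / x0)^2)
        else exp(params[["sigman"]] * ((xp - x0) / x0)^2)
  unname(params[["gxb"]] * md)
}

#' Normalized active tension of a myofilament state
#'
#' Overlap-weighted strain contribution of the attached cross-bridge
#' populations, normalized so that full duty at the power-stroke strain
#' gives tension near 1; clamped at zero (no negative reported tension).
#' Exactly zero when no cross-bridges are attached.
#'
#' @param state a [myo_state()].
#' @param SL sarcomere length (um).
#' @param params a [myofilament_params()].
#' @return normalized tension (dimensionless, >= 0).
#' @export
active_tension <- function(state, SL = 2.0, params = myofilament_params()) {
  o <- overlap_fractions(SL, params)
  fp <- params[["fapp"]]; gp <- params[["gapp"]]; hh <- params[["hf"]]
  hbb <- params[["hb"]]; gg <- params[["gxb"]]
  denom <- fp * hh + gg * hh + gg * gp + hbb * fp + hbb * gp + gg * fp
  duty_post <- fp * hh / denom
  raw <- o[["thick"]] *
    (state[["XB_PreR"]] * state[["xXB_PreR"]] +
       state[["XB_PostR"]] * state[["xXB_PostR"]]) /
    (params[["x0"]] * duty_post)
  max(raw, 0)
}

#' Contractile ATP consumption rate of a myofilament state
#'
#' The detachment-flux convention: current detachment rate `g_xbT` times
#' the thick-filament single-overlap fraction times the attached
#' post-rotation fraction (each completed detachment of a post-rotation
#' bridge hydrolyses one ATP).
#'
#' @param state a [myo_state()].
#' @param SL sarcomere length (um).
#' @param params a [myofilament_params()].
#' @return ATP consumption rate (s^-1).
#' @export
atp_rate <- function(state, SL = 2.0, params = myofilament_params()) {
  o <- overlap_fractions(SL, params)
  gxb_of_state(state, params) * o[["thick"]] * state[["XB_PostR"]]
}

#' Activation-time-shifted calcium drive
#'
#' Evaluates a calcium template at `(t - eat) mod cl`; before the node's
#' first activation the diastolic (cycle-start) level is returned.
#'
#' @param template a `ca_template` from [make_ca_template()].
#' @param eat the node's electrical activation time (ms); `NA` is rejected
#'   (such nodes are excluded from mechanics).
#' @param t time or vector of times (ms).
#' @return Ca_i (mM) at each `t`.
#' @export
shifted_ca_drive <- function(template, eat, t) {
  if (is.na(eat)) stop("node has no activation time; excluded from mechanics")
  cl <- template$cl
  ca <- numeric(length(t))
  pre <- t < eat
  ca[pre] <- template$ca[1]
  if (any(!pre)) {
    ph <- (t[!pre] - eat) %% cl
    ca[!pre] <- approx(template$time, template$ca, xout = ph, rule = 2)$y
  }
  ca
}

#' Run a myofilament instance over a sampled calcium drive
#'
#' @param ca_drive Ca_i samples (mM) at uniform spacing `dt`.
#' @param dt sample/integration step (ms).
#' @param SL fixed sarcomere length (um) or one value per sample.
#' @param params a [myofilament_params()].
#' @param state0 initial [myo_state()].
#' @param sample_every store every this-many steps.
#' @return object of class `tension_trace`: data.frame `time_ms`,
#'   `tension`, `atp_rate` with attributes `pool_err` and `final_state`.
#' @export
run_myofilament <- function(ca_drive, dt = 0.1, SL = 2.0,
                            params = myofilament_params(),
                            state0 = myo_state(params), sample_every = 1L) {
  out <- rice_run_cpp(as.numeric(state0), as.numeric(params),
                      ca_drive * 1000, SL, dt, as.integer(sample_every))
  df <- data.frame(time_ms = out$time, tension = pmax(out$tension, 0),
                   atp_rate = out$atp)
  structure(df, class = c("tension_trace", "data.frame"),
            pool_err = out$pool_err,
            final_state = structure(stats::setNames(out$final_state,
                                                    rice_state_names),
                                    class = "myo_state"),
            g_xbT = out$g_xbT, states = out$states)
}

#' Cycle ATP consumption of an ensemble of tension traces
#'
#' Per-node time integral of the ATP rate over one cycle, summed over
#' nodes and divided by the cycle duration; reported as a rate (s^-1).
#'
#' @param traces a `tension_trace` or list of them.
#' @param cl cycle length (ms).
#' @return node-summed cycle-average ATP consumption rate (s^-1).
#' @export
integrate_atp <- function(traces, cl) {
  if (inherits(traces, "tension_trace")) traces <- list(traces)
  total <- 0
  for (tr in traces) {
    if (max(tr$time_ms) - min(tr$time_ms) < cl - 1e-9)
      stop("trace shorter than the cycle")
    w <- tr$time_ms <= min(tr$time_ms) + cl + 1e-9
    tt <- tr$time_ms[w] / 1000  # s
    r <- tr$atp_rate[w]
    total <- total + sum(diff(tt) * (r[-1] + r[-length(r)]) / 2) / (cl / 1000)
  }
  total
}
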