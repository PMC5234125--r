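# Monodomain propagation on fixture geometries: diffusion coefficients from
# cellular resistivity, paced tissue runs, activation-map extraction, EAT
# duration, conduction-velocity measurement and resistivity calibration.

#' Tissue conduction parameters
#'
#' Per-axis cellular resistivity and surface-to-volume ratio together with
#' the membrane capacitance per area set the monodomain diffusion
#' coefficients D_a = 1/(rho_a S_a Cm).
#'
#' @param rho cellular resistivity per axis (Ohm cm); length 1 or 3.
#' @param S surface-to-volume ratio per axis (cm^-1); length 1 or 3.
#' @param Cm membrane capacitance per area (uF/cm^2).
#' @return object of class `tissue_params`.
#' @export
tissue_params <- function(rho = 162, S = 2000, Cm = 2) {
  rho <- rep_len(as.numeric(rho), 3)
  S <- rep_len(as.numeric(S), 3)
  if (any(rho <= 0) || any(S <= 0) || Cm <= 0)
    stop("rho, S and Cm must all be positive")
  structure(list(rho = rho, S = S, Cm = Cm), class = "tissue_params")
}

#' Monodomain diffusion coefficients
#'
#' D_a = 1/(rho_a S_a Cm), converted to cm^2/ms (Ohm x Farad = second).
#'
#' @param tparams a [tissue_params()].
#' @return numeric length-3 vector (cm^2/ms).
#' @export
diffusion_coefficients <- function(tparams) {
  stopifnot(inherits(tparams, "tissue_params"))
  D <- 1000 / (tparams$rho * tparams$S * tparams$Cm)
  if (any(!is.finite(D) | D <= 0)) stop("non-finite diffusion coefficient")
  D
}

cfl_limit <- function(tparams, geom, active_axes) {
  D <- diffusion_coefficients(tparams) * active_axes
  1 / sum(2 * D / geom$dx^2)
}

active_axes_of <- function(geom) {
  switch(geom$kind,
         cable = c(1, 0, 0), sheet = c(1, 1, 0),
         slab = c(1, 1, 1), shell = c(1, 1, 1))
}

region_codes_of <- function(geom) {
  match(geom$nodes$region, c("endo", "mid", "epi")) - 1L
}

params_matrix <- function(overrides = list()) {
  vapply(c("endo", "mid", "epi"),
         function(r) cell_params(r, overrides)$values,
         numeric(length(tp06_param_names)))
}

tissue_field_init <- function(geom, overrides = list()) {
  matrix(as.numeric(cell_state()), nrow = length(tp06_state_names),
         ncol = geom$n)
}

#' One operator-split monodomain step
#'
#' Reaction (per-node ionic step) followed by explicit diffusion with
#' no-flux boundaries. Intended for small fields and step-level testing;
#' full runs use [run_tissue_paced()].
#'
#' @param field list with `states` (19 x n matrix) and `t` (ms).
#' @param geom a `tissue_geometry`.
#' @param tparams a [tissue_params()].
#' @param stim per-node stimulus current (pA/pF), recycled to n.
#' @param dt step (ms).
#' @param cell_overrides cell-constant overrides applied to all regions
#'   (set all conductances and SR rates to zero to isolate diffusion).
#' @return updated field.
#' @export
step_tissue <- function(field, geom, tparams, stim = 0, dt = 0.02,
                        cell_overrides = list()) {
  lim <- cfl_limit(tparams, geom, active_axes_of(geom))
  if (dt > lim)
    stop(sprintf("dt = %g ms violates the diffusion stability limit %.4g ms",
                 dt, lim))
  n <- geom$n
  states <- field$states
  stim <- rep_len(stim, n)
  pm <- params_matrix(cell_overrides)
  reg <- region_codes_of(geom)
  new <- states
  for (i in seq_len(n)) {
    out <- tp06_step_cpp(states[, i], pm[, reg[i] + 1L], reg[i], stim[i], dt)
    new[, i] <- out$state
  }
  # diffusion on V with no-flux boundaries (missing neighbours drop out)
  D <- diffusion_coefficients(tparams) * active_axes_of(geom) / geom$dx^2
  V <- states[1, ]
  lap <- numeric(n)
  for (a in 1:3) {
    if (D[a] == 0) next
    for (side in 1:2) {
      j <- geom$nbr[, 2 * (a - 1) + side] + 1L
      ok <- j > 0
      lap[ok] <- lap[ok] + D[a] * (V[j[ok]] - V[ok])
    }
  }
  new[1, ] <- new[1, ] + dt * lap
  list(states = new, t = field$t + dt, laplacian = lap)
}

#' Run a paced monodomain tissue simulation
#'
#' Advances the full field under the given pacing protocol, extracting a
#' per-cycle activation map. The activation time of a node is its first
#' upward crossing of the threshold after cycle onset (linearly
#' interpolated); Purkinje-terminal stimulus sites are assigned their
#' commanded onsets, so the map minimum equals the protocol onset.
#'
#' @param geom a `tissue_geometry`.
#' @param tparams a [tissue_params()].
#' @param protocol a `sinus_protocol` (or planar protocol).
#' @param duration total simulated time (ms).
#' @param dt step (ms); checked against the diffusion stability limit.
#' @param threshold activation threshold (mV).
#' @param cell_overrides optional cell-constant overrides.
#' @param probe_nodes optional node ids whose V(t) is recorded.
#' @param probe_every record every this-many steps.
#' @param site_eat_convention assign stimulus sites their commanded onset
#'   as activation time (default TRUE).
#' @param init optional 19 x n initial state matrix.
#' @return list with `maps` (one `eat_map` per cycle), `final_state`,
#'   `probe` (time/V), and `n_cycles`.
#' @export
run_tissue_paced <- function(geom, tparams, protocol, duration,
                             dt = 0.02, threshold = 0,
                             cell_overrides = list(),
                             probe_nodes = integer(), probe_every = 10L,
                             site_eat_convention = TRUE, init = NULL) {
  stopifnot(inherits(geom, "tissue_geometry"),
            inherits(protocol, "sinus_protocol"))
  if (!nrow(protocol$sites)) stop("protocol has no stimulus sites")
  if (!all(protocol$sites$node %in% geom$nodes$id))
    stop("protocol sites must lie on the geometry")
  lim <- cfl_limit(tparams, geom, active_axes_of(geom))
  if (dt > lim)
    stop(sprintf("dt = %g ms violates the diffusion stability limit %.4g ms",
                 dt, lim))
  if (dt > 0.05) stop("dt exceeds the 0.05 ms reaction stability limit")
  D <- diffusion_coefficients(tparams) * active_axes_of(geom) / geom$dx^2
  init <- if (is.null(init)) tissue_field_init(geom) else init
  # each Purkinje terminal excites a small tissue ball (a point source
  # cannot depolarize 3D tissue against the diffusive load)
  sites <- protocol$sites
  r <- protocol$stim_radius
  if (is.null(r) || is.na(r)) r <- 0
  if (r > 0) {
    ex <- lapply(seq_len(nrow(sites)), function(s) {
      d <- sqrt((geom$nodes$x - sites$x[s])^2 + (geom$nodes$y - sites$y[s])^2 +
                  (geom$nodes$z - sites$z[s])^2)
      data.frame(node = geom$nodes$id[d <= r + 1e-12],
                 onset_ms = sites$onset_ms[s])
    })
    ex <- do.call(rbind, ex)
    ex <- ex[order(ex$onset_ms), ]
    ex <- ex[!duplicated(ex$node), ]  # earliest onset wins
  } else {
    ex <- sites[, c("node", "onset_ms")]
  }
  out <- tp06_run_tissue_cpp(
    init, region_codes_of(geom), params_matrix(cell_overrides), geom$nbr, D,
    as.integer(ex$node) - 1L, ex$onset_ms,
    protocol$stim_delay, protocol$amplitude, protocol$duration,
    protocol$cl, duration, dt, threshold,
    as.integer(probe_nodes) - 1L, as.integer(probe_every),
    FALSE)
  if (out$blowup_step >= 0)
    stop("numerical blow-up (|V| > 200 mV) at t = ",
         out$blowup_step * dt, " ms")
  ncyc <- out$n_cycles
  maps <- lapply(seq_len(ncyc), function(cyc) {
    eat <- out$eat[, cyc]
    if (site_eat_convention) {
      # Purkinje-surrogate convention: a terminal's activation time is its
      # commanded onset, so the map minimum equals the protocol onset
      eat[sites$node] <- sites$onset_ms
    }
    new_eat_map(geom, eat, onset = (cyc - 1) * protocol$cl,
                threshold = threshold)
  })
  if (ncyc > 1) {
    lost <- which(!is.na(out$eat[, 1]) & is.na(out$eat[, ncyc]))
    if (length(lost))
      warning("node(s) failed to re-activate by the final cycle: ",
              paste(utils::head(lost, 5), collapse = ", "),
              if (length(lost) > 5) " ..." else "")
  }
  list(maps = maps, final_state = out$final_state,
       probe = list(time = out$probe_time, V = out$probe_V),
       n_cycles = ncyc)
}

new_eat_map <- function(geom, eat, onset, threshold) {
  df <- data.frame(node = geom$nodes$id, x = geom$nodes$x, y = geom$nodes$y,
                   z = geom$nodes$z, eat_ms = eat)
  structure(df, class = c("eat_map", "data.frame"),
            onset = onset, threshold = threshold)
}

#' Extract an activation map from a voltage trace
#'
#' Per-node first upward threshold crossing after the cycle onset, linearly
#' interpolated between samples; nodes never crossing are flagged absent
#' (`NA`).
#'
#' @param V nodes x time matrix of membrane potential (mV).
#' @param time sample times (ms).
#' @param threshold activation threshold (mV); default 0.
#' @param cycle_onset cycle onset (ms); crossings before it are ignored.
#' @param geom optional `tissue_geometry` supplying coordinates.
#' @return an `eat_map` data.frame (`node`, `x`, `y`, `z`, `eat_ms`
#'   relative to cycle onset).
#' @export
activation_map <- function(V, time, threshold = 0, cycle_onset = 0,
                           geom = NULL) {
  if (is.null(dim(V))) V <- matrix(V, nrow = 1)
  n <- nrow(V)
  eat <- rep(NA_real_, n)
  use <- which(time >= cycle_onset)
  for (i in seq_len(n)) {
    v <- V[i, use]
    k <- which(v[-length(v)] < threshold & v[-1] >= threshold)
    if (length(k)) {
      k <- k[1]
      t0 <- time[use][k]; t1 <- time[use][k + 1]
      tc <- t0 + (t1 - t0) * (threshold - v[k]) / (v[k + 1] - v[k])
      eat[i] <- tc - cycle_onset
    }
  }
  if (is.null(geom)) {
    df <- data.frame(node = seq_len(n), x = NA_real_, y = NA_real_,
                     z = NA_real_, eat_ms = eat)
    structure(df, class = c("eat_map", "data.frame"),
              onset = cycle_onset, threshold = threshold)
  } else {
    new_eat_map(geom, eat, cycle_onset, threshold)
  }
}

#' Duration of electrical activation
#'
#' The latest activation time on the map, measured from cycle onset (a map
#' whose last node depolarizes 120 ms into the cycle has an EAT duration of
#' 120 ms).
#'
#' @param map an `eat_map`.
#' @return duration (ms).
#' @export
eat_duration <- function(map) {
  e <- map$eat_ms[!is.na(map$eat_ms)]
  if (!length(e)) stop("activation map has no activated nodes")
  max(e)
}

#' Conduction velocity between two activated points
#'
#' Euclidean distance divided by the activation-time difference (Eq. of
#' motion of the wavefront: v = d / t).
#'
#' @param map an `eat_map` with coordinates.
#' @param point_a,point_b node ids on the map.
#' @return conduction velocity (cm/s).
#' @export
measure_cv <- function(map, point_a, point_b) {
  ra <- map[map$node == point_a, ]; rb <- map[map$node == point_b, ]
  if (!nrow(ra) || !nrow(rb)) stop("point not on map")
  if (is.na(ra$eat_ms) || is.na(rb$eat_ms)) stop("both points must be activated")
  d <- sqrt((ra$x - rb$x)^2 + (ra$y - rb$y)^2 + (ra$z - rb$z)^2)
  if (d == 0) stop("points coincide (d = 0)")
  dt_ms <- abs(rb$eat_ms - ra$eat_ms)
  if (dt_ms == 0) stop("equal activation times (infinite velocity)")
  d / dt_ms * 1000
}

#' Measure planar conduction velocity on a cable fixture
#'
#' Stimulates the low-x face and measures velocity between the nodes at
#' 25% and 75% of the cable length, avoiding stimulus and boundary
#' artifacts.
#'
#' @param geom a cable `tissue_geometry`.
#' @param tparams a [tissue_params()].
#' @param dt step (ms).
#' @param duration run length (ms); by default long enough for traversal.
#' @param threshold activation threshold (mV).
#' @return list `cv` (cm/s, `NA` on conduction failure), `map`.
#' @export
cable_cv <- function(geom, tparams, dt = 0.02, duration = NULL,
                     threshold = 0) {
  L <- max(geom$nodes$x)
  if (is.null(duration)) {
    Dx <- diffusion_coefficients(tparams)[1]
    # traversal allowance with 30% margin; velocity scales like sqrt(D)
    cv_est <- 70 * sqrt(Dx / 1.543e-3)
    duration <- min(580, max(80, 40 + 1300 * L / cv_est))
  }
  proto <- make_planar_protocol(geom, onset = 0, cl = 600)
  run <- run_tissue_paced(geom, tparams, proto, duration = duration, dt = dt,
                          threshold = threshold, site_eat_convention = FALSE)
  map <- run$maps[[1]]
  n <- geom$n
  a <- round(0.25 * (n - 1)) + 1L
  b <- round(0.75 * (n - 1)) + 1L
  cv <- tryCatch(measure_cv(map, a, b), error = function(e) NA_real_)
  list(cv = cv, map = map, points = c(a, b))
}

#' Calibrate cellular resistivity to a target conduction velocity
#'
#' Bisection over resistivity on the supplied cable geometry until the
#' measured planar velocity is within `tol` of the target. Conduction
#' velocity decreases monotonically in resistivity over the bracket, which
#' is asserted on the initial endpoints.
#'
#' @param target_cv target velocity (cm/s).
#' @param geom cable `tissue_geometry` to calibrate on.
#' @param tparams_template a [tissue_params()] supplying S and Cm (and the
#'   starting resistivity, used only for its anisotropy ratios).
#' @param tol relative tolerance on the achieved velocity (default 1%).
#' @param bracket resistivity search interval (Ohm cm).
#' @param dt step (ms).
#' @param max_iter bisection cap.
#' @return list `rho` (Ohm cm), `cv` (cm/s), `iterations`.
#' @export
calibrate_resistivity <- function(target_cv, geom, tparams_template,
                                  tol = 0.01, bracket = c(60, 4000),
                                  dt = 0.02, max_iter = 40) {
  f <- function(rho) {
    tp <- tissue_params(rho = rho, S = tparams_template$S,
                        Cm = tparams_template$Cm)
    cable_cv(geom, tp, dt = dt)$cv
  }
  lo <- bracket[1]; hi <- bracket[2]
  cv_lo <- f(lo); cv_hi <- f(hi)
  if (is.na(cv_lo)) stop("conduction fails at the lower resistivity bracket")
  if (cv_lo < target_cv)
    stop(sprintf("target %.4g cm/s above achievable %.4g cm/s at rho = %g",
                 target_cv, cv_lo, lo))
  if (!is.na(cv_hi) && cv_hi >= cv_lo)
    stop("conduction velocity not decreasing over the bracket")
  if (!is.na(cv_hi) && cv_hi > target_cv)
    stop(sprintf("target %.4g cm/s below achievable range (cv = %.4g at rho = %g)",
                 target_cv, cv_hi, hi))
  it <- 0L; cv_mid <- NA_real_; mid <- NA_real_
  while (it < max_iter) {
    it <- it + 1L
    mid <- sqrt(lo * hi)  # velocity ~ rho^(-1/2): bisect in log space
    cv_mid <- f(mid)
    if (!is.na(cv_mid) && abs(cv_mid - target_cv) / target_cv <= tol) break
    if (is.na(cv_mid) || cv_mid < target_cv) hi <- mid else lo <- mid
  }
  if (is.na(cv_mid) || abs(cv_mid - target_cv) / target_cv > tol)
    stop(sprintf("calibration did not converge: target %.4g cm/s (conduction %s below rho = %g)",
                 target_cv,
                 if (is.na(cv_mid)) "fails" else sprintf("reaches only %.4g cm/s", cv_mid),
                 mid))
  list(rho = mid, cv = cv_mid, iterations = it)
}

#' Write an activation map as CSV
#'
#' @param map an `eat_map`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_eat_map <- function(map, path) {
  df <- as.data.frame(map)
  names(df) <- c("node_id", "x", "y", "z", "eat_ms")
  write_atomic_csv(df, path)
}
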