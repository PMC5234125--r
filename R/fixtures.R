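# Synthetic fixtures: tissue geometries with transmural layers, the
# Purkinje-surrogate sinus-pacing protocol, and calcium-transient templates.
# Everything is generated in code; no external data is required.

#' Fixture geometry specification
#'
#' Describes a regular Cartesian fixture standing in for an imaging-derived
#' ventricular mesh: a 1D cable, a 2D sheet, a 3D slab, or a truncated
#' half-ellipsoidal shell with endo/mid/epi transmural layers.
#'
#' @param kind one of `"cable"`, `"sheet"`, `"slab"`, `"shell"`.
#' @param dims lengths in cm: `cable` length; `sheet` (Lx, Ly); `slab`
#'   (Lx, Ly, Lz); `shell` outer semi-axes (a, b, c).
#' @param dx grid spacing (cm); must divide every dimension.
#' @param layer_fractions transmural fractions (endo, mid, epi) summing to 1.
#'   Layers run along the last axis for cable/sheet/slab (endocardium at the
#'   low-coordinate face) and along normalized wall depth for the shell.
#' @param inner_ratio shell only: inner semi-axes as a fraction of the outer.
#' @return object of class `fixture_spec`.
#' @export
fixture_spec <- function(kind = c("cable", "sheet", "slab", "shell"),
                         dims, dx,
                         layer_fractions = c(endo = 0.3, mid = 0.4, epi = 0.3),
                         inner_ratio = 0.6) {
  kind <- match.arg(kind)
  need <- c(cable = 1L, sheet = 2L, slab = 3L, shell = 3L)[[kind]]
  if (length(dims) != need)
    stop(kind, " fixtures need ", need, " dimension(s)")
  if (dx <= 0) stop("dx must be positive")
  r <- dims / dx
  if (any(abs(r - round(r)) > 1e-9))
    stop("dx = ", dx, " cm does not divide dimension(s) ",
         paste(dims[abs(r - round(r)) > 1e-9], collapse = ", "))
  lf <- layer_fractions
  if (length(lf) != 3 || abs(sum(lf) - 1) > 1e-9 || any(lf < 0))
    stop("layer_fractions must be 3 non-negative values summing to 1")
  names(lf) <- c("endo", "mid", "epi")
  if (kind == "shell" && (inner_ratio <= 0 || inner_ratio >= 1))
    stop("inner_ratio must be in (0, 1)")
  structure(list(kind = kind, dims = dims, dx = dx, layer_fractions = lf,
                 inner_ratio = inner_ratio),
            class = "fixture_spec")
}

layer_of <- function(depth, lf) {
  # depth in [0,1]: 0 at the endocardial face/surface, 1 at the epicardial one
  ifelse(depth < lf[["endo"]], "endo",
         ifelse(depth < lf[["endo"]] + lf[["mid"]], "mid", "epi"))
}

#' Build a tissue geometry from a fixture specification
#'
#' Produces the node table (coordinates in cm, transmural region label) and
#' the 6-neighbour adjacency used by the monodomain stencil. Deterministic:
#' identical specifications yield identical geometries.
#'
#' @param spec a [fixture_spec()].
#' @return object of class `tissue_geometry`: list with `nodes` (data.frame
#'   `id`, `x`, `y`, `z`, `region`, `depth`), `nbr` (n x 6 matrix of 0-based
#'   neighbour indices, -1 where the stencil leaves the domain), `dx`,
#'   `kind`, `n`.
#' @export
make_geometry <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  dx <- spec$dx
  lf <- spec$layer_fractions
  dims3 <- c(spec$dims, rep(0, 3 - length(spec$dims)))
  if (spec$kind == "shell") {
    # grid spans the full ellipse in x/y and the apex-to-base half in z
    dims3 <- c(2 * spec$dims[1], 2 * spec$dims[2], spec$dims[3])
  }
  nd <- round(dims3 / dx) + 1L  # grid points per axis (>=1)
  nx <- nd[1]; ny <- nd[2]; nz <- nd[3]
  ix <- rep(seq_len(nx) - 1L, times = ny * nz)
  iy <- rep(rep(seq_len(ny) - 1L, each = nx), times = nz)
  iz <- rep(seq_len(nz) - 1L, each = nx * ny)
  x <- ix * dx; y <- iy * dx; z <- iz * dx

  if (spec$kind == "shell") {
    # truncated half-ellipsoid: outer semi-axes (a,b,c), proportional inner
    # surface at `inner_ratio`, apex at z = 0, base plane at z = c.
    a <- spec$dims[1]; b <- spec$dims[2]; cc <- spec$dims[3]
    s <- spec$inner_ratio
    xc <- x - a; yc <- y - b; zc <- z - cc  # centre at (a, b, c)
    m <- sqrt((xc / a)^2 + (yc / b)^2 + (zc / cc)^2)
    inside <- m <= 1 & m >= s & z <= cc + 1e-12
    depth <- (m - s) / (1 - s)  # 0 at inner (endo) surface, 1 at outer
  } else {
    inside <- rep(TRUE, length(x))
    axis_len <- spec$dims[length(spec$dims)]
    u <- switch(spec$kind, cable = x, sheet = y, slab = z)
    depth <- if (axis_len > 0) u / axis_len else rep(0, length(x))
  }

  keep <- which(inside)
  n <- length(keep)
  if (n < 2) stop("degenerate geometry: fewer than 2 nodes")
  full_to_sub <- integer(nx * ny * nz)
  full_to_sub[keep] <- seq_len(n)

  lin <- function(i, j, k) 1L + i + nx * (j + ny * k)
  nbr <- matrix(-1L, n, 6)
  ii <- ix[keep]; jj <- iy[keep]; kk <- iz[keep]
  off <- list(c(-1L, 0L, 0L), c(1L, 0L, 0L), c(0L, -1L, 0L), c(0L, 1L, 0L),
              c(0L, 0L, -1L), c(0L, 0L, 1L))
  for (a_ in 1:6) {
    o <- off[[a_]]
    i2 <- ii + o[1]; j2 <- jj + o[2]; k2 <- kk + o[3]
    ok <- i2 >= 0 & i2 < nx & j2 >= 0 & j2 < ny & k2 >= 0 & k2 < nz
    idx <- rep(0L, n)
    idx[ok] <- full_to_sub[lin(i2[ok], j2[ok], k2[ok])]
    nbr[, a_] <- ifelse(ok & idx > 0, idx - 1L, -1L)
  }

  d <- pmin(pmax(depth[keep], 0), 1)
  nodes <- data.frame(
    id = seq_len(n), x = x[keep], y = y[keep], z = z[keep],
    region = layer_of(d, lf), depth = d, stringsAsFactors = FALSE
  )
  structure(list(nodes = nodes, nbr = nbr, dx = dx, kind = spec$kind,
                 dims = spec$dims, n = n, spec = spec),
            class = "tissue_geometry")
}

#' Endocardial nodes of a geometry
#'
#' Candidate Purkinje-terminal sites: nodes labelled `endo`.
#' @param geom a `tissue_geometry`.
#' @return integer node ids.
#' @export
endocardial_nodes <- function(geom) {
  geom$nodes$id[geom$nodes$region == "endo"]
}

#' Purkinje-surrogate sinus-pacing protocol
#'
#' Samples early-activation sites from the endocardial nodes (seeded,
#' reproducible) and assigns each site an onset equal to the global onset
#' plus its path distance from the earliest site divided by the Purkinje
#' path speed. Path distance is approximated by Euclidean distance on
#' these convex fixtures.
#'
#' @param geom a `tissue_geometry` with endocardial nodes.
#' @param n_sites number of Purkinje-terminal sites (>= 1).
#' @param onset global onset of the earliest terminal (ms into the cycle).
#' @param purkinje_speed path speed along the surrogate network (cm/s).
#' @param cl cycle length (ms).
#' @param amplitude,duration stimulus current (pA/pF) and duration (ms).
#' @param stim_delay delay between a terminal's activation time and the
#'   myocardial stimulus current it delivers (ms).
#' @param stim_radius radius (cm) of the tissue ball each terminal
#'   stimulates; a point source cannot excite 3D tissue against the
#'   diffusive load.
#' @param seed RNG seed for site sampling.
#' @return object of class `sinus_protocol`: data.frame `sites` (node, x,
#'   y, z, onset_ms) plus protocol attributes.
#' @export
make_sinus_protocol <- function(geom, n_sites = 12, onset = 20,
                                purkinje_speed = 200, cl = 600,
                                amplitude = -52, duration = 1,
                                stim_delay = 5, stim_radius = 0.12,
                                seed = 101) {
  if (n_sites < 1) stop("n_sites must be >= 1")
  cand <- endocardial_nodes(geom)
  if (!length(cand)) stop("geometry has no endocardial nodes")
  picked <- local_seed(seed, {
    if (length(cand) <= n_sites) cand else sort(sample(cand, n_sites))
  })
  nd <- geom$nodes[picked, ]
  # earliest terminal: the sampled node closest to the apex-most point
  # (lowest z, then lowest x) for a reproducible anchor
  anchor <- order(nd$z, nd$x, nd$y)[1]
  d <- sqrt((nd$x - nd$x[anchor])^2 + (nd$y - nd$y[anchor])^2 +
              (nd$z - nd$z[anchor])^2)
  onsets <- onset + d / purkinje_speed * 1000
  sites <- data.frame(node = nd$id, x = nd$x, y = nd$y, z = nd$z,
                      onset_ms = onsets)
  sites <- sites[order(sites$onset_ms, sites$node), ]
  rownames(sites) <- NULL
  structure(list(sites = sites, cl = cl, amplitude = amplitude,
                 duration = duration, stim_delay = stim_delay,
                 stim_radius = stim_radius,
                 purkinje_speed = purkinje_speed, onset = onset,
                 seed = seed),
            class = "sinus_protocol")
}

#' Planar pacing protocol for cables and sheets
#'
#' Stimulates the full low-x face at a single onset; used for
#' conduction-velocity measurement.
#'
#' @param geom a `tissue_geometry`.
#' @param onset stimulus onset (ms into the cycle).
#' @param n_layers number of grid layers (in x) to stimulate; by default
#'   enough layers to cover ~0.06 cm, so the stimulated width is a fixed
#'   physical depth independent of grid spacing.
#' @inheritParams make_sinus_protocol
#' @return a `sinus_protocol` whose sites are the stimulated face.
#' @export
make_planar_protocol <- function(geom, onset = 0, n_layers = NULL, cl = 600,
                                 amplitude = -52, duration = 1) {
  if (is.null(n_layers)) n_layers <- max(2L, as.integer(round(0.06 / geom$dx)))
  xs <- sort(unique(geom$nodes$x))[seq_len(n_layers)]
  idx <- geom$nodes$id[geom$nodes$x %in% xs]
  sites <- data.frame(node = idx, x = geom$nodes$x[idx], y = geom$nodes$y[idx],
                      z = geom$nodes$z[idx], onset_ms = onset)
  structure(list(sites = sites, cl = cl, amplitude = amplitude,
                 duration = duration, stim_delay = 0, stim_radius = 0,
                 purkinje_speed = NA_real_, onset = onset, seed = NA),
            class = "sinus_protocol")
}

#' Calcium-transient template from a converged single-cell run
#'
#' Paces a single cell of the requested transmural type to convergence and
#' extracts the final-beat intracellular calcium trace on a fixed grid.
#' Rejects non-converged runs (beat-to-beat diastolic drift above 2%).
#'
#' @param region `"endo"`, `"mid"` or `"epi"`.
#' @param cl cycle length (ms).
#' @param n_prebeats pre-pacing beats before the extracted beat (>= 20).
#' @param dt integration step (ms).
#' @param sample_dt template sampling interval (ms).
#' @param overrides cell-parameter overrides.
#' @return object of class `ca_template`: list `time` (ms), `ca` (mM),
#'   `cl`, `region`.
#' @export
make_ca_template <- function(region, cl = 600, n_prebeats = 24, dt = 0.02,
                             sample_dt = 0.1, overrides = list()) {
  if (n_prebeats < 20) stop("need at least 20 pre-pacing beats")
  params <- cell_params(region, overrides)
  proto <- stimulus_protocol(cl = cl, n_beats = n_prebeats + 1)
  sample_every <- max(1L, as.integer(round(sample_dt / dt)))
  tr <- run_paced_cell(params, proto, dt = dt, sample_every = sample_every)
  per_beat <- as.integer(round(cl / sample_dt))
  dia <- function(b) tr$Ca_i[(b - 1) * per_beat + 1]
  drift <- abs(dia(n_prebeats + 1) - dia(n_prebeats)) / dia(n_prebeats)
  if (drift > 0.02)
    stop(sprintf("calcium not converged: diastolic drift %.1f%% > 2%%",
                 100 * drift))
  sel <- seq.int(n_prebeats * per_beat + 1, (n_prebeats + 1) * per_beat)
  ca <- tr$Ca_i[sel]
  if (abs(ca[length(ca)] - ca[1]) > 0.05 * max(ca[1], 1e-9) + 0.05 * (max(ca) - min(ca)))
    warning("template does not return to near-diastolic level by cycle end")
  structure(list(time = (sel - sel[1]) * sample_dt, ca = ca, cl = cl,
                 region = region, sample_dt = sample_dt, drift = drift),
            class = "ca_template")
}

#' Frozen fixture suite used by the reference analyses
#'
#' Ships the fixed fixture specifications and protocol constants used by
#' the package's reference experiments: the conduction-velocity calibration
#' cables and the sweep shell with its sinus protocol.
#'
#' @return named list with elements `cv_cable` (2 cm epicardial cable,
#'   dx = 0.025 cm, resistivity preset 162 Ohm cm), `cv_cable_fine`
#'   (dx halved), `calib_cable` (cable matched to the sweep shell spacing),
#'   and `sweep_shell` (truncated half-ellipsoid shell plus sinus-protocol
#'   constants: onset 20 ms, Purkinje speed 200 cm/s, CL 600 ms).
#' @export
reference_fixture_suite <- function() {
  list(
    cv_cable = list(
      spec = fixture_spec("cable", dims = 2.0, dx = 0.025,
                          layer_fractions = c(0, 0, 1)),
      rho = 162, dt = 0.02
    ),
    cv_cable_fine = list(
      spec = fixture_spec("cable", dims = 2.0, dx = 0.0125,
                          layer_fractions = c(0, 0, 1)),
      rho = 162, dt = 0.02
    ),
    calib_cable = list(
      spec = fixture_spec("cable", dims = 2.0, dx = 0.05,
                          layer_fractions = c(0, 0, 1)),
      rho = 162, dt = 0.02
    ),
    sweep_shell = list(
      spec = fixture_spec("shell", dims = c(0.6, 0.6, 0.75), dx = 0.05,
                          layer_fractions = c(endo = 0.3, mid = 0.4, epi = 0.3),
                          inner_ratio = 0.6),
      protocol = list(n_sites = 12, onset = 20, purkinje_speed = 200,
                      cl = 600, stim_delay = 5, seed = 101),
      dt = 0.02
    )
  )
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's state.
local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
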