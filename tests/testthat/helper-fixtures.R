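# Small fixtures shared across test files; everything built in code.

# Cell-constant overrides that null every membrane conductance and SR flux
# (I_ion identically zero, concentrations frozen).
null_cell_overrides <- function() {
  as.list(stats::setNames(rep(0, 16), c(
    "G_Na", "G_K1", "G_to", "G_Kr", "G_Ks", "G_CaL", "k_NaCa", "P_NaK",
    "G_pCa", "G_pK", "G_bCa", "G_bNa",
    "V_maxup", "V_rel", "V_leak", "V_xfer")))
}

tiny_cable <- function(len = 1.0, dx = 0.05) {
  make_geometry(fixture_spec("cable", dims = len, dx = dx,
                             layer_fractions = c(0, 0, 1)))
}

tiny_slab <- function() {
  make_geometry(fixture_spec("slab", dims = c(0.3, 0.3, 0.2), dx = 0.05,
                             layer_fractions = c(endo = 0.4, mid = 0.3,
                                                 epi = 0.3)))
}

# Cheap configuration for end-to-end plumbing tests: short electrical run,
# few mechanical cycles, small ensemble.
cheap_config <- function() {
  cfg <- default_config()
  cfg$sweep$electrical_duration <- 1200
  cfg$sweep$n_cycles <- 6
  cfg$circulation$ensemble_size <- 24
  cfg$fixtures$protocol$n_sites <- 4
  cfg
}

# Synthetic activation map over a tiny slab (no tissue run needed).
synthetic_map <- function(geom = tiny_slab(), spread = 20) {
  eat <- 20 + spread * (geom$nodes$x + geom$nodes$y + geom$nodes$z) /
    max(geom$nodes$x + geom$nodes$y + geom$nodes$z)
  structure(
    data.frame(node = geom$nodes$id, x = geom$nodes$x, y = geom$nodes$y,
               z = geom$nodes$z, eat_ms = eat),
    class = c("eat_map", "data.frame"), onset = 0, threshold = 0)
}
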