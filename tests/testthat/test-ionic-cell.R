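# Single-myocyte electrophysiology.

test_that("currents vanish under zero conductances and at reversal potentials", {
  params0 <- cell_params("epi", null_cell_overrides())
  cur <- ionic_currents(cell_state(), params0)
  expect_true(all(abs(cur) < 1e-12))

  # V clamped to the K+ Nernst potential with only the inward rectifier
  # conductance nonzero: its driving force, hence the current, is zero
  p <- cell_params("epi", null_cell_overrides())
  p$values[["G_K1"]] <- 5.405
  st <- cell_state()
  Ek <- 8314.472 * 310 / 96485.3415 * log(p$values[["K_o"]] / st[["K_i"]])
  st2 <- cell_state(list(V = Ek))
  cur <- ionic_currents(st2, p)
  expect_equal(unname(cur[["I_K1"]]), 0, tolerance = 1e-12)
})

test_that("total ionic current sums exactly the 12 membrane currents", {
  cur <- stats::setNames(rep(1, 12), cardiomech:::membrane_current_names)
  expect_identical(total_ionic_current(cur), 12)
  expect_identical(total_ionic_current(0 * cur), 0)
  cur2 <- stats::setNames(c(1, -1, 2, -2, 3, -3, 4, -4, 5, -5, 6, -6),
                          cardiomech:::membrane_current_names)
  expect_identical(total_ionic_current(cur2), 0)
  # SR fluxes present in the vector must not contribute
  cur3 <- c(cur, I_leak = 100, I_up = 50, I_rel = -30)
  expect_identical(total_ionic_current(cur3), 12)
  expect_error(total_ionic_current(cur[1:5]), "12 membrane-current")
})

test_that("step_cell follows the membrane equation and SR balance signs", {
  params0 <- cell_params("epi", null_cell_overrides())
  st <- cell_state()
  # I_ion = 0, I_stim = 0: V unchanged
  out <- step_cell(st, params0, I_stim = 0, dt = 0.02)
  expect_equal(out$state[["V"]], st[["V"]], tolerance = 1e-12)
  expect_equal(out$I_ion, 0)
  # linearity: Cm-normalized -52 pA/pF for 1 ms depolarizes by +52 mV
  out <- step_cell(st, params0, I_stim = -52, dt = 1, max_dt = 1)
  expect_equal(out$state[["V"]] - st[["V"]], 52, tolerance = 1e-10)
  # SR balance sign: with leak and release off and uptake on, SR calcium
  # strictly increases
  pup <- cell_params("epi", utils::modifyList(null_cell_overrides(),
                                              list(V_maxup = 0.006375)))
  out <- step_cell(st, pup, I_stim = 0, dt = 0.02)
  expect_gt(out$state[["Ca_SR"]], st[["Ca_SR"]])
  # stability limit enforced
  expect_error(step_cell(st, params0, dt = 0.1), "outside")
})

test_that("non-finite state is rejected with the offending field named", {
  expect_error(cell_state(list(Na_i = NaN)), "Na_i")
  st <- cell_state()
  st[["V"]] <- Inf
  expect_error(ionic_currents(st, cell_params("epi")), "V")
})

test_that("sodium channels are closed at rest: |I_Na| < |I_K1|", {
  p <- cell_params("epi")
  # settle to rest without stimulation, then inspect currents
  tr <- run_paced_cell(p, stimulus_protocol(cl = 1000, amplitude = 0,
                                            n_beats = 2))
  st <- structure(tr$final_state, class = "cell_state")
  cur <- ionic_currents(st, p)
  expect_lt(abs(cur[["I_Na"]]), abs(cur[["I_K1"]]))
})

test_that("paced epicardial cell shows a physiological action potential", {
  p <- cell_params("epi")
  tr <- run_paced_cell(p, stimulus_protocol(cl = 600, n_beats = 3))
  m <- ap_metrics(tr)
  expect_true(m$ap_detected)
  expect_gt(m$V_rest, -88); expect_lt(m$V_rest, -83)
  expect_gt(m$V_peak, 10);  expect_lt(m$V_peak, 45)
  expect_gt(m$Ca_amplitude, 0)
  # no stimulus: no action potential
  tr0 <- run_paced_cell(p, stimulus_protocol(cl = 600, amplitude = 0,
                                             n_beats = 1))
  expect_lt(max(tr0$V) - min(tr0$V), 5)
  expect_false(ap_metrics(tr0)$ap_detected)
})

test_that("mid-myocardial APD90 exceeds epicardial APD90", {
  apd <- vapply(c("mid", "epi"), function(r) {
    tr <- run_paced_cell(cell_params(r), stimulus_protocol(cl = 600,
                                                           n_beats = 3))
    ap_metrics(tr)$APD90
  }, numeric(1))
  expect_gt(apd[["mid"]], apd[["epi"]])
})

test_that("ap_metrics handles constructed traces and flags absent APs", {
  tt <- seq(0, 600, by = 1)
  V <- ifelse(tt >= 50 & tt < 350, 15, -85)
  m <- ap_metrics(list(time = tt, V = V), cl = 600)
  expect_true(m$ap_detected)
  expect_equal(m$APD90, 300, tolerance = 1.5)
  m0 <- ap_metrics(list(time = tt, V = rep(-85, length(tt))), cl = 600)
  expect_false(m0$ap_detected)
  expect_true(is.na(m0$APD90))
})

test_that("gates stay in [0,1] and concentrations positive over 10 beats", {
  tr <- run_paced_cell(cell_params("epi"),
                       stimulus_protocol(cl = 600, n_beats = 10))
  expect_gte(tr$gate_min, 0)
  expect_lte(tr$gate_max, 1)
  expect_gt(tr$conc_min, 0)
})

test_that("paced runs are deterministic and converge under dt refinement", {
  p <- cell_params("epi")
  proto <- stimulus_protocol(cl = 600, n_beats = 3)
  tr1 <- run_paced_cell(p, proto)
  tr2 <- run_paced_cell(p, proto)
  expect_identical(tr1$V, tr2$V)
  expect_identical(tr1$final_state, tr2$final_state)
  a1 <- ap_metrics(tr1)$APD90
  a2 <- ap_metrics(run_paced_cell(p, proto, dt = 0.01,
                                  sample_every = 100L))$APD90
  expect_lt(abs(a1 - a2), 1)
})
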