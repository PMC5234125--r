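# Windkessel circulation, ventricle surrogate, and the coupled run.

test_that("failing preset stiffens compliances by 10% exactly, once", {
  base <- circulation_params()
  fail <- apply_failing_condition(base)
  comp <- c("C_sa", "C_sv", "C_pa", "C_pv")
  expect_equal(as.numeric(fail[comp]), 0.9 * as.numeric(base[comp]),
               tolerance = 1e-12)
  res <- setdiff(names(base), comp)
  expect_identical(as.numeric(fail[res]), as.numeric(base[res]))
  expect_error(apply_failing_condition(fail), "already applied")
  # a unit compliance becomes 0.9
  one <- circulation_params(overrides = list(C_sa = 1))
  expect_equal(apply_failing_condition(one)[["C_sa"]], 0.9,
               tolerance = 1e-12)
})

test_that("ventricle surrogate pressure is passive-null and linear in gain", {
  lv <- ventricle_params("lv")
  expect_equal(ventricle_pressure(lv, 0, lv[["V_rest"]]), 0,
               tolerance = 1e-12)
  lv2 <- ventricle_params("lv", list(alpha = 2 * lv[["alpha"]]))
  V <- 70; T <- 0.4
  pa1 <- ventricle_pressure(lv, T, V) - ventricle_pressure(lv, 0, V)
  pa2 <- ventricle_pressure(lv2, T, V) - ventricle_pressure(lv2, 0, V)
  expect_equal(pa2, 2 * pa1, tolerance = 1e-10)
  expect_gt(ventricle_pressure(lv, 0.5, V), ventricle_pressure(lv, 0.4, V))
  expect_error(ventricle_pressure(lv, 0, -5), "positive")
})

test_that("a closed, gradient-free circulation does not move volume", {
  cp <- circulation_params()
  v0 <- hemo_state_init(cp, P = c(sa = 10, sv = 10, pa = 10, pv = 10))
  out <- step_circulation(v0, cp, P_lv = 10, P_rv = 10, dt = 0.1)
  expect_equal(as.numeric(out$volumes), as.numeric(v0), tolerance = 1e-12)
  expect_true(all(out$flows == 0))
})

test_that("an isolated compartment discharges as exp(-t/RC)", {
  # arterial compartment draining through R_sys into an (effectively)
  # fixed-pressure venous sink; valves held shut by extreme pressures
  R <- 1.0; C <- 1.0
  cp <- circulation_params(overrides = list(
    R_sys = R, C_sa = C, C_sv = 1e9, R_pul = 1e12))
  v <- hemo_state_init(cp, P = c(sa = 100, sv = 0, pa = 10, pv = 0))
  dt <- 0.1; nstep <- 5000  # 0.5 s
  # ventricular pressures chosen to hold every valve shut throughout
  for (i in seq_len(nstep))
    v <- step_circulation(v, cp, P_lv = 5, P_rv = 5, dt = dt)$volumes
  Psa <- (v[["V_sa"]] - cp[["V0_sa"]]) / cp[["C_sa"]]
  expect_equal(Psa, 100 * exp(-0.5 / (R * C)), tolerance = 0.005 * 100 * exp(-0.5))
})

test_that("the coupled engine matches repeated single R-level steps", {
  # with no active tension the engine reduces to the passive circulation;
  # both paths use the same step core and must agree to round-off
  cfg <- cheap_config()
  cfg$circulation$sl_coupling <- FALSE
  map <- synthetic_map()
  tmpl0 <- list(time = seq(0, 599.9, by = 0.1), ca = rep(0, 6000), cl = 600,
                region = "epi")
  templates <- list(endo = tmpl0, mid = tmpl0, epi = tmpl0)
  for (r in names(templates)) class(templates[[r]]) <- "ca_template"
  h <- suppressWarnings(run_cardiac_cycles(map, tiny_slab(), n_cycles = 3,
                                           config = cfg,
                                           templates = templates))
  cp <- circulation_params(failing = TRUE)
  ip <- cfg$circulation$init_pressures
  v <- hemo_state_init(cp, P = c(sa = ip$sa, sv = ip$sv, pa = ip$pa,
                                 pv = ip$pv))
  lv <- ventricle_params("lv"); rv <- ventricle_params("rv")
  # the engine trace's final row is one output stride before the end
  for (i in seq_len(1800 / 0.1 - 10)) {
    plv <- ventricle_pressure(lv, 0, v[["V_lv"]])
    prv <- ventricle_pressure(rv, 0, v[["V_rv"]])
    v <- step_circulation(v, cp, plv, prv, dt = 0.1)$volumes
  }
  # the engine's myofilament bank contributes a ~1e-4 transient tension
  # while the initially-permissive fraction deactivates, so agreement is
  # to ~1e-7 relative rather than exact
  expect_equal(unname(utils::tail(h$trace$V_lv, 1)), unname(v[["V_lv"]]),
               tolerance = 1e-6)
})

test_that("total blood volume is conserved and runs are deterministic", {
  cfg <- cheap_config()
  map <- synthetic_map()
  h1 <- suppressWarnings(run_cardiac_cycles(map, tiny_slab(), n_cycles = 4,
                                            config = cfg))
  h2 <- suppressWarnings(run_cardiac_cycles(map, tiny_slab(), n_cycles = 4,
                                            config = cfg))
  expect_lt(h1$conservation_err, 1e-6)
  expect_identical(h1$trace, h2$trace)
  expect_identical(h1$last_cycle, h2$last_cycle)
  expect_true(all(h1$trace$V_lv > 0))
})

test_that("synchronous activation yields at least the dispersed peak pressure", {
  cfg <- cheap_config()
  geom <- tiny_slab()
  uni <- synthetic_map(geom, spread = 0)
  dis <- synthetic_map(geom, spread = 40)
  # equalize means: shift the uniform map to the dispersed mean
  uni$eat_ms <- uni$eat_ms + (mean(dis$eat_ms) - mean(uni$eat_ms))
  h_u <- suppressWarnings(run_cardiac_cycles(uni, geom, n_cycles = 5,
                                             config = cfg))
  h_d <- suppressWarnings(run_cardiac_cycles(dis, geom, n_cycles = 5,
                                             config = cfg))
  expect_gte(max(h_u$last_cycle$P_lv), max(h_d$last_cycle$P_lv))
})

test_that("steady-state check measures end-diastolic drift", {
  fake <- list(edv = c(90, 90, 90, 90))
  expect_true(steady_state_check(fake)$converged)
  expect_equal(steady_state_check(fake)$drift, 0)
  grow <- list(edv = c(80, 85, 90, 95))
  expect_false(steady_state_check(grow)$converged)
  expect_error(steady_state_check(list(edv = c(1, 2))), "3 cycles")
})

test_that("stroke work equals the enclosed PV-loop area", {
  # rectangular loop: P 0 <-> 100 mmHg between V 50 and 80 mL
  V <- c(seq(80, 50, length.out = 50), rep(50, 10),
         seq(50, 80, length.out = 50), rep(80, 10))
  P <- c(rep(100, 50), seq(100, 0, length.out = 10),
         rep(0, 50), seq(0, 100, length.out = 10))
  expect_equal(cardiomech:::pv_loop_area(P, V), 3000, tolerance = 0.005 * 3000)
})
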