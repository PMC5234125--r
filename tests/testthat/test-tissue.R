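# Monodomain conduction, activation maps and resistivity calibration.

test_that("diffusion coefficients follow 1/(rho S Cm) with unit conversion", {
  D <- diffusion_coefficients(tissue_params(rho = 162, S = 2000, Cm = 2))
  # hand arithmetic: 162 * 2000 * 2e-6 Ohm F / cm^2 = 0.648 s/cm^2
  expect_equal(D[1], 1e-3 / 0.648, tolerance = 1e-12)
  D2 <- diffusion_coefficients(tissue_params(rho = 324, S = 2000, Cm = 2))
  expect_equal(D2[1], D[1] / 2, tolerance = 1e-12)
  Da <- diffusion_coefficients(tissue_params(rho = c(100, 200, 100)))
  expect_equal(Da[1] / Da[2], 2, tolerance = 1e-12)
  expect_error(tissue_params(rho = 0), "positive")
  expect_error(tissue_params(S = -1), "positive")
})

test_that("diffusion stencil is null on uniform fields and conservative", {
  geom <- tiny_cable(len = 0.5)
  tp <- tissue_params()
  field <- list(states = cardiomech:::tissue_field_init(geom), t = 0)
  out <- step_tissue(field, geom, tp, stim = 0, dt = 0.02,
                     cell_overrides = null_cell_overrides())
  expect_true(all(abs(out$laplacian) < 1e-12))
  expect_equal(out$states[1, ], field$states[1, ], tolerance = 1e-12)

  # one elevated interior node: neighbours rise, sum(V - V_rest) conserved
  field$states[1, 6] <- field$states[1, 6] + 10
  base <- sum(field$states[1, ] - (-86.2))
  out <- step_tissue(field, geom, tp, dt = 0.02,
                     cell_overrides = null_cell_overrides())
  expect_gt(out$states[1, 5], -86.2)
  expect_gt(out$states[1, 7], -86.2)
  expect_lt(out$states[1, 6], field$states[1, 6])
  expect_lt(abs(sum(out$states[1, ] - (-86.2)) - base) / abs(base), 1e-10)
  # CFL guard
  expect_error(step_tissue(field, geom, tp, dt = 1), "stability limit")
})

test_that("activation maps record interpolated threshold crossings", {
  tt <- seq(0, 100, by = 0.5)
  # node 1 ramps through 0 mV at exactly t = 37; node 2 never crosses
  V <- rbind(-80 + (80 / 37) * tt, rep(-80, length(tt)))
  map <- activation_map(V, tt, threshold = 0)
  expect_equal(map$eat_ms[1], 37, tolerance = 0.5)
  expect_true(is.na(map$eat_ms[2]))
  expect_equal(eat_duration(map), map$eat_ms[1])

  # synthetic planar wave at speed c: activation linear in distance
  geom <- tiny_cable(len = 1.0, dx = 0.05)
  c_cm_ms <- 0.05  # 50 cm/s
  x <- geom$nodes$x
  Vw <- t(vapply(x, function(xi) {
    ifelse(tt > xi / c_cm_ms, 20, -80)
  }, numeric(length(tt))))
  mapw <- activation_map(Vw, tt, threshold = 0, geom = geom)
  fit <- stats::coef(stats::lm(mapw$eat_ms ~ x))
  expect_equal(unname(fit[2]), 1 / c_cm_ms, tolerance = 0.05)
  cv <- measure_cv(mapw, mapw$node[3], mapw$node[15])
  expect_equal(cv, 50, tolerance = 0.051 * 50)
})

test_that("eat_duration is the map maximum from cycle onset", {
  map <- structure(data.frame(node = 1:3, x = 0, y = 0, z = 0,
                              eat_ms = c(20, 60, 120)),
                   class = c("eat_map", "data.frame"), onset = 0)
  expect_equal(eat_duration(map), 120)
  map$eat_ms <- rep(20, 3)
  expect_equal(eat_duration(map), 20)
  map$eat_ms[3] <- 130
  expect_equal(eat_duration(map), 130)
  map$eat_ms <- NA_real_
  expect_error(eat_duration(map), "no activated nodes")
})

test_that("measure_cv implements distance over activation-time difference", {
  map <- structure(data.frame(node = 1:2, x = c(0, 1.4), y = 0, z = 0,
                              eat_ms = c(10, 30)),
                   class = c("eat_map", "data.frame"))
  expect_equal(measure_cv(map, 1, 2), 70, tolerance = 1e-12)
  map$x[2] <- 0
  expect_error(measure_cv(map, 1, 2), "coincide")
  map$x[2] <- 1.4; map$eat_ms[2] <- 10
  expect_error(measure_cv(map, 1, 2), "equal activation")
})

test_that("paced tissue runs validate the protocol and are deterministic", {
  geom <- tiny_cable(len = 1.0)
  tp <- tissue_params(rho = 162)
  proto <- make_planar_protocol(geom, onset = 0, cl = 600)
  bad <- proto; bad$sites <- bad$sites[0, ]
  expect_error(run_tissue_paced(geom, tp, bad, duration = 10), "no stimulus")

  r1 <- run_tissue_paced(geom, tp, proto, duration = 60)
  r2 <- run_tissue_paced(geom, tp, proto, duration = 60)
  expect_identical(r1$maps[[1]]$eat_ms, r2$maps[[1]]$eat_ms)
  expect_true(all(!is.na(r1$maps[[1]]$eat_ms)))
})

test_that("conduction velocity decreases with resistivity on a cable", {
  geom <- tiny_cable(len = 2.0, dx = 0.05)
  cv1 <- cable_cv(geom, tissue_params(rho = 162))$cv
  cv2 <- cable_cv(geom, tissue_params(rho = 162 * 1.67))$cv
  expect_false(is.na(cv1)); expect_false(is.na(cv2))
  expect_gt(cv1, cv2)
})

test_that("resistivity calibration hits the target velocity", {
  geom <- tiny_cable(len = 2.0, dx = 0.05)
  cal <- calibrate_resistivity(45, geom, tissue_params(), tol = 0.01)
  expect_lt(abs(cal$cv - 45) / 45, 0.01)
  tp <- tissue_params(rho = cal$rho)
  expect_equal(cable_cv(geom, tp)$cv, cal$cv, tolerance = 1e-9)
  # unreachable target: above the bracket's achievable range
  expect_error(calibrate_resistivity(500, geom, tissue_params()), "above")
})

test_that("sinus protocol on a slab activates fully with onset as minimum", {
  geom <- tiny_slab()
  proto <- make_sinus_protocol(geom, n_sites = 3, onset = 20,
                               stim_delay = 5, seed = 7, cl = 300)
  run <- run_tissue_paced(geom, tissue_params(rho = 162), proto,
                          duration = 300)
  map <- run$maps[[1]]
  expect_true(all(!is.na(map$eat_ms)))
  expect_identical(min(map$eat_ms), 20)
  # non-site nodes activate only after the delayed myocardial stimulus
  others <- setdiff(map$node, proto$sites$node)
  expect_true(all(map$eat_ms[others] > 25))
})
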