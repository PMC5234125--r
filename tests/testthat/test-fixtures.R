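# Synthetic fixture generators: geometries, protocols, calcium templates.

test_that("cable node counts and spacing validation", {
  g <- make_geometry(fixture_spec("cable", dims = 2.0, dx = 0.025,
                                  layer_fractions = c(0, 0, 1)))
  expect_identical(g$n, 81L)
  expect_true(all(g$nodes$region == "epi"))
  expect_error(fixture_spec("cable", dims = 2.0, dx = 0.3), "divide")
  expect_error(fixture_spec("cable", dims = 2.0, dx = 0.025,
                            layer_fractions = c(0.5, 0.2, 0.2)), "summing")
})

test_that("slab layer proportions track the requested fractions", {
  g <- make_geometry(fixture_spec("slab", dims = c(0.3, 0.3, 0.5), dx = 0.05,
                                  layer_fractions = c(0.3, 0.4, 0.3)))
  tab <- table(g$nodes$region) / g$n
  layer <- 1 / (0.5 / 0.05 + 1)  # one grid layer's share along the axis
  expect_lt(abs(tab[["endo"]] - 0.3), layer + 1e-9)
  expect_lt(abs(tab[["mid"]] - 0.4), layer + 1e-9)
  expect_lt(abs(tab[["epi"]] - 0.3), layer + 1e-9)
})

test_that("geometry generation is deterministic", {
  spec <- fixture_spec("shell", dims = c(0.6, 0.6, 0.75), dx = 0.05)
  g1 <- make_geometry(spec); g2 <- make_geometry(spec)
  expect_identical(g1$nodes, g2$nodes)
  expect_identical(g1$nbr, g2$nbr)
})

test_that("shell geometry has a closed transmural layering", {
  g <- make_geometry(reference_fixture_suite()$sweep_shell$spec)
  expect_setequal(unique(g$nodes$region), c("endo", "mid", "epi"))
  expect_true(all(g$nodes$depth >= 0 & g$nodes$depth <= 1))
  # endocardial nodes lie strictly inside the epicardial surface
  expect_true(all(g$nodes$depth[g$nodes$region == "endo"] <
                    min(g$nodes$depth[g$nodes$region == "epi"])))
})

test_that("sinus protocol encodes the Purkinje path speed exactly", {
  g <- make_geometry(reference_fixture_suite()$sweep_shell$spec)
  pr <- make_sinus_protocol(g, n_sites = 8, onset = 20,
                            purkinje_speed = 200, seed = 11)
  s <- pr$sites
  expect_identical(min(s$onset_ms), 20)
  anchor <- s[which.min(s$onset_ms), ]
  for (i in which(s$onset_ms > anchor$onset_ms)) {
    d <- sqrt((s$x[i] - anchor$x)^2 + (s$y[i] - anchor$y)^2 +
                (s$z[i] - anchor$z)^2)
    implied <- d / ((s$onset_ms[i] - anchor$onset_ms) / 1000)
    expect_equal(implied, 200, tolerance = 1e-9)
  }
  # single site: one onset equal to the global onset
  pr1 <- make_sinus_protocol(g, n_sites = 1, onset = 20, seed = 11)
  expect_identical(pr1$sites$onset_ms, 20)
  # reproducible sampling; different seeds explore different sites
  pr2 <- make_sinus_protocol(g, n_sites = 8, onset = 20, seed = 11)
  expect_identical(pr$sites, pr2$sites)
  # no endocardial nodes -> rejection
  cab <- tiny_cable()
  expect_error(make_sinus_protocol(cab, n_sites = 2), "no endocardial")
})

test_that("calcium templates are converged, unimodal and cycle-long", {
  tm <- make_ca_template("epi", cl = 600)
  expect_true(all(tm$ca >= 0))
  expect_equal(max(tm$time), 600 - tm$sample_dt, tolerance = 1e-9)
  ipk <- which.max(tm$ca)
  expect_gt(ipk, 1); expect_lt(ipk, length(tm$ca))
  # monotone rise to the peak and decay after it (coarse unimodality)
  expect_true(all(diff(tm$ca[1:ipk]) >= -1e-7))
  expect_lt(tm$ca[length(tm$ca)], tm$ca[ipk] / 2)
  expect_lt(tm$drift, 0.02)
  expect_error(make_ca_template("epi", n_prebeats = 5), "at least 20")
  tm2 <- make_ca_template("epi", cl = 600)
  expect_identical(tm$ca, tm2$ca)
})

test_that("the frozen fixture suite carries the reference constants", {
  s1 <- reference_fixture_suite()
  s2 <- reference_fixture_suite()
  expect_identical(s1, s2)
  expect_equal(s1$cv_cable$rho, 162)
  expect_equal(s1$cv_cable$spec$dx, 0.025)
  expect_equal(s1$cv_cable_fine$spec$dx, 0.0125)
  expect_equal(s1$sweep_shell$protocol$onset, 20)
  expect_equal(s1$sweep_shell$protocol$cl, 600)
  expect_equal(s1$sweep_shell$protocol$purkinje_speed, 200)
})
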