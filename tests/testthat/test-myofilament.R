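# Cross-bridge dynamics, tension, ATP rate, and activation-shifted drives.

test_that("regulatory pool is conserved over 1e5 random-calcium steps", {
  set.seed(42)
  ca <- stats::runif(1e5, 0, 0.005)  # 0-5 uM in mM
  tr <- run_myofilament(ca, dt = 0.1, SL = 2.0, sample_every = 1000L)
  expect_lt(attr(tr, "pool_err"), 1e-8)
  expect_true(all(tr$tension >= 0))
  expect_true(all(tr$atp_rate >= 0))
})

test_that("no calcium means no cross-bridge activation", {
  tr <- run_myofilament(rep(0, 10000), dt = 0.1, SL = 2.0)
  fs <- attr(tr, "final_state")
  expect_lt(fs[["XB_PreR"]] + fs[["XB_PostR"]], 1e-3)
})

test_that("tension is zero without attached bridges and monotone in XB_PostR", {
  st0 <- myo_state(overrides = list(N_xB = 1, P_xB = 0))
  expect_identical(active_tension(st0), 0)
  t1 <- active_tension(myo_state(overrides = list(
    N_xB = 0.8, P_xB = 0.1, XB_PreR = 0.05, XB_PostR = 0.05)))
  t2 <- active_tension(myo_state(overrides = list(
    N_xB = 0.8, P_xB = 0.05, XB_PreR = 0.05, XB_PostR = 0.10)))
  expect_gt(t2, t1)
})

test_that("ATP rate is the detachment flux times thick-filament overlap", {
  p <- myofilament_params()
  # post-rotation strain at x0 leaves the detachment rate at its base value
  st <- myo_state(overrides = list(N_xB = 0, P_xB = 0, XB_PreR = 0,
                                   XB_PostR = 1))
  sovf <- overlap_fractions(2.2, p)[["thick"]]
  expect_equal(atp_rate(st, SL = 2.2, p), p[["gxb"]] * sovf,
               tolerance = 1e-12)
  # halving the attached fraction halves the rate
  st2 <- myo_state(overrides = list(N_xB = 0.5, P_xB = 0, XB_PreR = 0,
                                    XB_PostR = 0.5))
  expect_equal(atp_rate(st2, SL = 2.2, p), 0.5 * p[["gxb"]] * sovf,
               tolerance = 1e-12)
  # doubling the base detachment rate doubles the ATP rate
  p2 <- myofilament_params(list(gxb = 140))
  expect_equal(atp_rate(st, SL = 2.2, p2), 2 * atp_rate(st, SL = 2.2, p),
               tolerance = 1e-12)
})

test_that("steady tension under saturating calcium matches the reference
          integration within 1%", {
  p <- myofilament_params()
  tr <- run_myofilament(rep(0.02, 20000), dt = 0.1, SL = 2.2)
  mine <- utils::tail(tr$tension, 1)
  y0 <- as.numeric(myo_state(p))
  parms <- list(p = p, ca_fn = function(t) 20, SL = 2.2)
  o <- deSolve::lsoda(y0, c(0, 2000), rice_rhs_R, parms,
                      rtol = 1e-10, atol = 1e-12)
  ref <- rice_reference_tension(o[nrow(o), -1], p, 2.2)
  expect_lt(abs(mine - ref) / ref, 0.01)
})

test_that("shifted calcium drive delays the template by the activation time", {
  tm <- make_ca_template("epi", cl = 600)
  tt <- seq(0, 599.9, by = 0.1)
  expect_equal(shifted_ca_drive(tm, 0, tt), tm$ca, tolerance = 1e-9)
  ca40 <- shifted_ca_drive(tm, 40, tt)
  expect_equal(tt[which.max(ca40)] - tt[which.max(tm$ca)], 40,
               tolerance = 0.2)
  expect_error(shifted_ca_drive(tm, NA, tt), "excluded")

  # two nodes activated 100 ms apart: tension peaks separate by 100 +- 2
  tr1 <- run_myofilament(shifted_ca_drive(tm, 20, tt), dt = 0.1, SL = 2.0)
  tr2 <- run_myofilament(shifted_ca_drive(tm, 120, tt), dt = 0.1, SL = 2.0)
  d <- tr2$time_ms[which.max(tr2$tension)] - tr1$time_ms[which.max(tr1$tension)]
  expect_equal(d, 100, tolerance = 2)
  # peak tension lags peak calcium
  expect_gt(tr1$time_ms[which.max(tr1$tension)], 20 + tt[which.max(tm$ca)])
})

test_that("cycle ATP integration sums nodes and matches refined quadrature", {
  tt <- seq(0, 600, by = 0.1)
  const <- structure(data.frame(time_ms = tt, tension = 0,
                                atp_rate = rep(3, length(tt))),
                     class = c("tension_trace", "data.frame"))
  expect_equal(integrate_atp(rep(list(const), 5), cl = 600), 15,
               tolerance = 1e-9)
  zero <- const; zero$atp_rate <- 0
  expect_equal(integrate_atp(zero, cl = 600), 0)
  short <- const[tt < 300, ]
  expect_error(integrate_atp(short, cl = 600), "shorter")

  # trapezoid at the default sampling vs a 10x-refined quadrature
  tm <- make_ca_template("epi", cl = 600)
  tr <- run_myofilament(rep(shifted_ca_drive(tm, 0, tt[-length(tt)]), 2),
                        dt = 0.1, SL = 2.0)
  last <- tr[tr$time_ms >= 600, ]
  last$time_ms <- last$time_ms - 600
  coarse <- integrate_atp(structure(last[seq(1, nrow(last), by = 10), ],
                                    class = class(tr)), cl = 599)
  fine <- integrate_atp(structure(last, class = class(tr)), cl = 599)
  expect_lt(abs(coarse - fine) / fine, 1e-3)
})

test_that("dispersing activation never raises the ensemble tension peak", {
  tm <- make_ca_template("epi", cl = 600)
  tt <- seq(0, 599.9, by = 0.1)
  ensemble_peak <- function(eats) {
    total <- 0
    for (e in eats)
      total <- total + run_myofilament(shifted_ca_drive(tm, e, tt),
                                       dt = 0.1, SL = 2.0)$tension
    max(total)
  }
  uniform <- ensemble_peak(c(40, 40, 40))
  spread1 <- ensemble_peak(c(20, 40, 60))
  spread2 <- ensemble_peak(c(0, 40, 80))
  expect_lte(spread1, uniform)
  expect_lte(spread2, spread1)
})

test_that("step_myofilament rejects out-of-range sarcomere lengths", {
  st <- myo_state()
  expect_error(step_myofilament(st, Ca_i = 0.001, SL = 3.0), "range")
  expect_error(step_myofilament(st, Ca_i = -1), "non-negative")
  out <- step_myofilament(st, Ca_i = 0.001, SL = 2.0)
  expect_s3_class(out$state, "myo_state")
  expect_lt(abs(sum(out$state[1:4]) - 1), 1e-8)
})
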