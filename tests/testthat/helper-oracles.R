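# Independent reference integrations used as oracles: the same published
# model equations, coded separately in R and integrated with deSolve's
# adaptive stiff solver rather than the package's fixed-step kernels.

# Derivatives of the human ventricular cell model for deSolve.
# y: named state in the package's layout; parms: list(p = named constant
# vector, region = "endo"/"mid"/"epi", istim = function(t) pA/pF).
tp06_rhs_R <- function(t, y, parms) {
  p <- parms$p
  region <- parms$region
  RTONF <- 8314.472 * 310 / 96485.3415
  FRDY <- 96485.3415
  CCELL <- 0.185

  V <- y[1]; m <- y[2]; h <- y[3]; j <- y[4]; xr1 <- y[5]; xr2 <- y[6]
  xs <- y[7]; r <- y[8]; s <- y[9]; d <- y[10]; f <- y[11]; f2 <- y[12]
  fcass <- y[13]; RR <- y[14]; Cai <- y[15]; CaSR <- y[16]; CaSS <- y[17]
  Nai <- y[18]; Ki <- y[19]

  Ek <- RTONF * log(p[["K_o"]] / Ki)
  Ena <- RTONF * log(p[["Na_o"]] / Nai)
  Eks <- RTONF * log((p[["K_o"]] + p[["pK_Na"]] * p[["Na_o"]]) /
                       (Ki + p[["pK_Na"]] * Nai))
  Eca <- 0.5 * RTONF * log(p[["Ca_o"]] / Cai)

  INa <- p[["G_Na"]] * m^3 * h * j * (V - Ena)
  vq <- 2 * (V - 15) / RTONF
  exq <- exp(vq)
  ICaL <- if (abs(V - 15) < 1e-6) {
    p[["G_CaL"]] * d * f * f2 * fcass * 2 * FRDY * (0.25 * CaSS - p[["Ca_o"]])
  } else {
    p[["G_CaL"]] * d * f * f2 * fcass * 4 * (V - 15) * (FRDY / RTONF) *
      (0.25 * CaSS * exq - p[["Ca_o"]]) / (exq - 1)
  }
  Ito <- p[["G_to"]] * r * s * (V - Ek)
  IKr <- p[["G_Kr"]] * sqrt(p[["K_o"]] / 5.4) * xr1 * xr2 * (V - Ek)
  IKs <- p[["G_Ks"]] * xs^2 * (V - Eks)
  xk1 <- V - Ek
  Ak1 <- 0.1 / (1 + exp(0.06 * (xk1 - 200)))
  Bk1 <- (3 * exp(0.0002 * (xk1 + 100)) + exp(0.1 * (xk1 - 10))) /
    (1 + exp(-0.5 * xk1))
  IK1 <- p[["G_K1"]] * Ak1 / (Ak1 + Bk1) * (V - Ek)
  nn <- p[["n_NaCa"]]
  INaCa <- p[["k_NaCa"]] * (1 / (p[["K_mNai"]]^3 + p[["Na_o"]]^3)) *
    (1 / (p[["K_mCa"]] + p[["Ca_o"]])) *
    (1 / (1 + p[["k_sat"]] * exp((nn - 1) * V / RTONF))) *
    (exp(nn * V / RTONF) * Nai^3 * p[["Ca_o"]] -
       exp((nn - 1) * V / RTONF) * p[["Na_o"]]^3 * Cai * 2.5)
  INaK <- p[["P_NaK"]] * (p[["K_o"]] / (p[["K_o"]] + p[["K_mK"]])) *
    (Nai / (Nai + p[["K_mNa"]])) /
    (1 + 0.1245 * exp(-0.1 * V / RTONF) + 0.0353 * exp(-V / RTONF))
  IpCa <- p[["G_pCa"]] * Cai / (p[["K_pCa"]] + Cai)
  IpK <- p[["G_pK"]] / (1 + exp((25 - V) / 5.98)) * (V - Ek)
  IbNa <- p[["G_bNa"]] * (V - Ena)
  IbCa <- p[["G_bCa"]] * (V - Eca)

  Istim <- parms$istim(t)
  Iion <- INa + IK1 + Ito + IKr + IKs + ICaL + INaCa + INaK + IpCa + IpK +
    IbCa + IbNa

  # gate kinetics
  AM <- 1 / (1 + exp((-60 - V) / 5))
  BM <- 0.1 / (1 + exp((V + 35) / 5)) + 0.10 / (1 + exp((V - 50) / 200))
  tau_m <- AM * BM
  m_inf <- 1 / (1 + exp((-56.86 - V) / 9.03))^2
  if (V >= -40) {
    AH <- 0; BH <- 0.77 / (0.13 * (1 + exp(-(V + 10.66) / 11.1)))
    AJ <- 0; BJ <- 0.6 * exp(0.057 * V) / (1 + exp(-0.1 * (V + 32)))
  } else {
    AH <- 0.057 * exp(-(V + 80) / 6.8)
    BH <- 2.7 * exp(0.079 * V) + 3.1e5 * exp(0.3485 * V)
    AJ <- (-2.5428e4 * exp(0.2444 * V) - 6.948e-6 * exp(-0.04391 * V)) *
      (V + 37.78) / (1 + exp(0.311 * (V + 79.23)))
    BJ <- 0.02424 * exp(-0.01052 * V) / (1 + exp(-0.1378 * (V + 40.14)))
  }
  tau_h <- 1 / (AH + BH)
  h_inf <- 1 / (1 + exp((V + 71.55) / 7.43))^2
  tau_j <- 1 / (AJ + BJ); j_inf <- h_inf
  xr1_inf <- 1 / (1 + exp((-26 - V) / 7))
  tau_xr1 <- 450 / (1 + exp((-45 - V) / 10)) * 6 / (1 + exp((V + 30) / 11.5))
  xr2_inf <- 1 / (1 + exp((V + 88) / 24))
  tau_xr2 <- 3 / (1 + exp((-60 - V) / 20)) * 1.12 / (1 + exp((V - 60) / 20))
  xs_inf <- 1 / (1 + exp((-5 - V) / 14))
  tau_xs <- 1400 / sqrt(1 + exp((5 - V) / 6)) / (1 + exp((V - 35) / 15)) + 80
  r_inf <- 1 / (1 + exp((20 - V) / 6))
  tau_r <- 9.5 * exp(-(V + 40)^2 / 1800) + 0.8
  if (region == "endo") {
    s_inf <- 1 / (1 + exp((V + 28) / 5))
    tau_s <- 1000 * exp(-(V + 67)^2 / 1000) + 8
  } else {
    s_inf <- 1 / (1 + exp((V + 20) / 5))
    tau_s <- 85 * exp(-(V + 45)^2 / 320) + 5 / (1 + exp((V - 20) / 5)) + 3
  }
  d_inf <- 1 / (1 + exp((-8 - V) / 7.5))
  tau_d <- (1.4 / (1 + exp((-35 - V) / 13)) + 0.25) *
    (1.4 / (1 + exp((V + 5) / 5))) + 1 / (1 + exp((50 - V) / 20))
  f_inf <- 1 / (1 + exp((V + 20) / 7))
  tau_f <- 1102.5 * exp(-(V + 27)^2 / 225) + 200 / (1 + exp((13 - V) / 10)) +
    180 / (1 + exp((V + 30) / 10)) + 20
  f2_inf <- 0.67 / (1 + exp((V + 35) / 7)) + 0.33
  tau_f2 <- 600 * exp(-(V + 25)^2 / 170) + 31 / (1 + exp((25 - V) / 10)) +
    16 / (1 + exp((V + 30) / 10))
  fcass_inf <- 0.6 / (1 + (CaSS / 0.05)^2) + 0.4
  tau_fcass <- 80 / (1 + (CaSS / 0.05)^2) + 2

  # calcium subsystem
  kCaSR <- p[["max_sr"]] - (p[["max_sr"]] - p[["min_sr"]]) /
    (1 + (p[["EC"]] / CaSR)^2)
  k1 <- p[["k1_prime"]] / kCaSR
  k2 <- p[["k2_prime"]] * kCaSR
  dRR <- p[["k4"]] * (1 - RR) - k2 * CaSS * RR
  sOO <- k1 * CaSS^2 * RR / (p[["k3"]] + k1 * CaSS^2)
  Irel <- p[["V_rel"]] * sOO * (CaSR - CaSS)
  Ileak <- p[["V_leak"]] * (CaSR - Cai)
  Iup <- p[["V_maxup"]] / (1 + p[["K_up"]]^2 / Cai^2)
  Ixfer <- p[["V_xfer"]] * (CaSS - Cai)

  bufsr <- 1 / (1 + p[["Buf_sr"]] * p[["K_bufsr"]] / (CaSR + p[["K_bufsr"]])^2)
  bufss <- 1 / (1 + p[["Buf_ss"]] * p[["K_bufss"]] / (CaSS + p[["K_bufss"]])^2)
  bufc <- 1 / (1 + p[["Buf_c"]] * p[["K_bufc"]] / (Cai + p[["K_bufc"]])^2)
  dCaSR <- bufsr * (Iup - Irel - Ileak)
  dCaSS <- bufss * (-Ixfer * (p[["Vc"]] / p[["Vss"]]) +
                      Irel * (p[["Vsr"]] / p[["Vss"]]) -
                      ICaL * CCELL / (2 * p[["Vss"]] * FRDY))
  dCai <- bufc * (-(IbCa + IpCa - 2 * INaCa) * CCELL / (2 * p[["Vc"]] * FRDY) -
                    (Iup - Ileak) * (p[["Vsr"]] / p[["Vc"]]) + Ixfer)
  dNai <- -(INa + IbNa + 3 * INaK + 3 * INaCa) * CCELL / (p[["Vc"]] * FRDY)
  dKi <- -(Istim + IK1 + Ito + IKr + IKs - 2 * INaK + IpK) * CCELL /
    (p[["Vc"]] * FRDY)

  list(c(
    -(Iion + Istim),
    (m_inf - m) / tau_m, (h_inf - h) / tau_h, (j_inf - j) / tau_j,
    (xr1_inf - xr1) / tau_xr1, (xr2_inf - xr2) / tau_xr2,
    (xs_inf - xs) / tau_xs, (r_inf - r) / tau_r, (s_inf - s) / tau_s,
    (d_inf - d) / tau_d, (f_inf - f) / tau_f, (f2_inf - f2) / tau_f2,
    (fcass_inf - fcass) / tau_fcass, dRR,
    dCai, dCaSR, dCaSS, dNai, dKi
  ))
}

# Integrate one stimulated beat with deSolve at tight tolerance, returning
# a sampled (time, V, Ca_i) trace.
tp06_reference_beat <- function(y0, params, cl = 600, stim_amp = -52,
                                stim_dur = 1, sample_dt = 0.05) {
  p <- params$values
  parms1 <- list(p = p, region = params$region,
                 istim = function(t) stim_amp)
  parms0 <- list(p = p, region = params$region, istim = function(t) 0)
  t1 <- seq(0, stim_dur, by = sample_dt)
  o1 <- deSolve::lsoda(as.numeric(y0), t1, tp06_rhs_R, parms1,
                       rtol = 1e-8, atol = 1e-10)
  y1 <- o1[nrow(o1), -1]
  t2 <- seq(stim_dur, cl, by = sample_dt)
  o2 <- deSolve::lsoda(as.numeric(y1), t2, tp06_rhs_R, parms0,
                       rtol = 1e-8, atol = 1e-10)
  tt <- c(o1[, 1], o2[-1, 1])
  V <- c(o1[, 2], o2[-1, 2])
  Cai <- c(o1[, 16], o2[-1, 16])
  list(time = tt, V = V, Ca_i = Cai)
}

# Myofilament derivatives for deSolve (fixed SL). Ca in uM; rates s^-1,
# time in ms.
rice_rhs_R <- function(t, y, parms) {
  p <- parms$p
  Ca <- parms$ca_fn(t)
  SL <- parms$SL
  N <- y[1]; P <- y[2]; A1 <- y[3]; A2 <- y[4]
  TL <- y[5]; TH <- y[6]; x1 <- y[7]; x2 <- y[8]

  ze <- min(p[["len_thick"]] / 2, SL / 2)
  cle <- max(SL / 2 - (SL - p[["len_thin"]]), p[["len_hbare"]] / 2)
  lo <- max(ze - cle, 0)
  sovft <- lo * 2 / (p[["len_thick"]] - p[["len_hbare"]])
  sovfn <- lo / p[["len_thin"]]

  dTL <- (p[["kon"]] * Ca * (1 - TL) - p[["koffL"]] * TL) / 1000
  dTH <- (p[["kon"]] * Ca * (1 - TH) - p[["koffH"]] * TH) / 1000
  trop <- (1 - sovfn) * TL + sovfn * TH
  permtot <- sqrt(1 / (1 + (p[["perm50"]] / max(trop, 1e-12))^p[["nperm"]]))
  inprmt <- min(1 / permtot, 100)
  knpT <- p[["knp"]] * permtot
  kpnT <- p[["kpn"]] * inprmt
  fappT <- p[["fapp"]]
  gappT <- p[["gapp"]] * (1 + (1 - sovft) * p[["gslmod"]])
  x0 <- p[["x0"]]
  hfmd <- min(exp(-sign(x1) * p[["hfmdc"]] * (x1 / x0)^2), 2)
  hfT <- p[["hf"]] * hfmd
  hbT <- p[["hb"]]
  gxbmd <- if (x2 < x0) exp(p[["sigmap"]] * ((x0 - x2) / x0)^2)
           else exp(p[["sigman"]] * ((x2 - x0) / x0)^2)
  gxbT <- p[["gxb"]] * gxbmd

  dN <- (-knpT * N + kpnT * P) / 1000
  dP <- (knpT * N - kpnT * P - fappT * P + gappT * A1 + gxbT * A2) / 1000
  dA1 <- (fappT * P - gappT * A1 - hfT * A1 + hbT * A2) / 1000
  dA2 <- (hfT * A1 - hbT * A2 - gxbT * A2) / 1000

  denom <- p[["fapp"]] * p[["hf"]] + p[["gxb"]] * p[["hf"]] +
    p[["gxb"]] * p[["gapp"]] + p[["hb"]] * p[["fapp"]] +
    p[["hb"]] * p[["gapp"]] + p[["gxb"]] * p[["fapp"]]
  dutyPre <- (p[["hb"]] * p[["fapp"]] + p[["gxb"]] * p[["fapp"]]) / denom
  dutyPost <- p[["fapp"]] * p[["hf"]] / denom
  dx1 <- (p[["xPsi"]] / dutyPre) *
    (-fappT * x1 + hbT * (x2 - x0 - x1)) / 1000
  dx2 <- (p[["xPsi"]] / dutyPost) * hfT * (x1 + x0 - x2) / 1000

  list(c(dN, dP, dA1, dA2, dTL, dTH, dx1, dx2))
}

rice_reference_tension <- function(y, p, SL) {
  ze <- min(p[["len_thick"]] / 2, SL / 2)
  cle <- max(SL / 2 - (SL - p[["len_thin"]]), p[["len_hbare"]] / 2)
  lo <- max(ze - cle, 0)
  sovft <- lo * 2 / (p[["len_thick"]] - p[["len_hbare"]])
  denom <- p[["fapp"]] * p[["hf"]] + p[["gxb"]] * p[["hf"]] +
    p[["gxb"]] * p[["gapp"]] + p[["hb"]] * p[["fapp"]] +
    p[["hb"]] * p[["gapp"]] + p[["gxb"]] * p[["fapp"]]
  dutyPost <- p[["fapp"]] * p[["hf"]] / denom
  sovft * (y[3] * y[7] + y[4] * y[8]) / (p[["x0"]] * dutyPost)
}

apd90_of <- function(time, V, cl) {
  ap_metrics(list(time = time, V = V), cl = cl)$APD90
}
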