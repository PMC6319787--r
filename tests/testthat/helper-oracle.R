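# Independent reference implementations used as oracles.
#
# oracleRhs: the TP06 right-hand side written directly from the published
# model equations in plain R (continuous form, no lookup tables).  Used
# with deSolve::lsoda to validate action potentials of the compiled
# integrator.
#
# oracleCable: a dense-matrix forward-Euler/Rush-Larsen integrator for a
# 1D cable, written in vectorized R.  It reproduces the production
# scheme (same update ordering, same tabulated-rate construction coded
# from scratch) so that agreement validates the tissue wiring: coupling
# matrix, no-flux boundaries, stimulus delivery and state bookkeeping.
#
# oracleWinding: brute-force phase-winding singularity detector.
# oracleEcg: direct double-loop dipole summation.

oracleRates <- function(V, prm) {
  sig <- function(x) 1 / (1 + exp(x))
  out <- list()
  out$m_inf <- sig((-56.86 - V) / 9.03)^2
  am <- sig((-60 - V) / 5)
  bm <- 0.1 * sig((V + 35) / 5) + 0.1 * sig((V - 50) / 200)
  out$m_tau <- am * bm
  out$h_inf <- sig((V + 71.55) / 7.43)^2
  if (V >= -40) {
    ah <- 0; bh <- 0.77 / (0.13 * (1 + exp(-(V + 10.66) / 11.1)))
    aj <- 0; bj <- 0.6 * exp(0.057 * V) / (1 + exp(-0.1 * (V + 32)))
  } else {
    ah <- 0.057 * exp(-(V + 80) / 6.8)
    bh <- 2.7 * exp(0.079 * V) + 3.1e5 * exp(0.3485 * V)
    aj <- (-25428 * exp(0.2444 * V) - 6.948e-6 * exp(-0.04391 * V)) *
      (V + 37.78) / (1 + exp(0.311 * (V + 79.23)))
    bj <- 0.02424 * exp(-0.01052 * V) / (1 + exp(-0.1378 * (V + 40.14)))
  }
  out$h_tau <- 1 / (ah + bh)
  out$j_inf <- out$h_inf
  out$j_tau <- 1 / (aj + bj)
  if (V < -40) {
    out$h_tau <- out$h_tau * prm[["tauhj_rec_scale"]]
    out$j_tau <- out$j_tau * prm[["tauhj_rec_scale"]]
  }
  out$xr1_inf <- sig((-26 - V) / 7)
  out$xr1_tau <- 450 * sig((-45 - V) / 10) * 6 * sig((V + 30) / 11.5)
  out$xr2_inf <- sig((V + 88) / 24)
  out$xr2_tau <- 3 * sig((-60 - V) / 20) * 1.12 * sig((V - 60) / 20)
  out$xs_inf <- sig((-5 - V) / 14)
  out$xs_tau <- 1400 / sqrt(1 + exp((5 - V) / 6)) * sig((V - 35) / 15) + 80
  out$r_inf <- sig((20 - V) / 6)
  out$r_tau <- 9.5 * exp(-(V + 40)^2 / 1800) + 0.8
  out$s_inf <- sig((V + 20) / 5)
  out$s_tau <- prm[["taus_scale"]] *
    (85 * exp(-(V + 45)^2 / 320) + 5 * sig((V - 20) / 5) + 3)
  out$d_inf <- sig((-8 - V) / 7.5)
  out$d_tau <- (1.4 * sig((-35 - V) / 13) + 0.25) * 1.4 * sig((V + 5) / 5) +
    sig((50 - V) / 20)
  out$f_inf <- sig((V + 20) / 7)
  out$f_tau <- prm[["tauf_scale"]] *
    (1102.5 * exp(-(V + 27)^2 / 225) + 200 * sig((13 - V) / 10) +
       180 * sig((V + 30) / 10) + 20)
  out$f2_inf <- 0.67 * sig((V + 35) / 7) + 0.33
  out$f2_tau <- 562 * exp(-(V + 27)^2 / 240) + 31 * sig((25 - V) / 10) +
    80 * sig((V + 30) / 10)
  out
}

oracleCurrents <- function(y, prm) {
  RTF <- prm[["Rgas"]] * prm[["Temp"]] / prm[["Faraday"]]
  F <- prm[["Faraday"]]
  ENa <- RTF * log(prm[["Nao"]] / y[["nai"]])
  EK <- RTF * log(prm[["Ko"]] / y[["ki"]])
  EKs <- RTF * log((prm[["Ko"]] + prm[["pKNa"]] * prm[["Nao"]]) /
                   (y[["ki"]] + prm[["pKNa"]] * y[["nai"]]))
  ECa <- 0.5 * RTF * log(prm[["Cao"]] / y[["cai"]])
  V <- y[["V"]]
  INa <- prm[["GNa"]] * y[["m"]]^3 * y[["h"]] * y[["j"]] * (V - ENa)
  x <- 2 * (V - 15) / RTF
  ICaL <- prm[["GCaL"]] * y[["d"]] * y[["f"]] * y[["f2"]] * y[["fcass"]] *
    4 * (V - 15) * F / RTF *
    (0.25 * y[["cass"]] * exp(x) - prm[["Cao"]]) / (exp(x) - 1)
  Ito <- prm[["Gto"]] * y[["r"]] * y[["s"]] * (V - EK)
  IKr <- prm[["GKr"]] * sqrt(prm[["Ko"]] / 5.4) * y[["xr1"]] * y[["xr2"]] *
    (V - EK)
  IKs <- prm[["GKs"]] * y[["xs"]]^2 * (V - EKs)
  aK1 <- 0.1 / (1 + exp(0.06 * (V - EK - 200)))
  bK1 <- (3 * exp(2e-4 * (V - EK + 100)) + exp(0.1 * (V - EK - 10))) /
    (1 + exp(-0.5 * (V - EK)))
  IK1 <- prm[["GK1"]] * aK1 / (aK1 + bK1) * (V - EK)
  INaCa <- prm[["kNaCa"]] *
    (exp(prm[["gamma"]] * V / RTF) * y[["nai"]]^3 * prm[["Cao"]] -
     exp((prm[["gamma"]] - 1) * V / RTF) * prm[["Nao"]]^3 * y[["cai"]] * 2.5) /
    ((prm[["KmNai"]]^3 + prm[["Nao"]]^3) * (prm[["KmCa"]] + prm[["Cao"]]) *
     (1 + prm[["ksat"]] * exp((prm[["gamma"]] - 1) * V / RTF)))
  INaK <- prm[["PNaK"]] * prm[["Ko"]] * y[["nai"]] /
    ((prm[["Ko"]] + prm[["KmK"]]) * (y[["nai"]] + prm[["KmNa"]])) /
    (1 + 0.1245 * exp(-0.1 * V / RTF) + 0.0353 * exp(-V / RTF))
  IpCa <- prm[["GpCa"]] * y[["cai"]] / (prm[["KpCa"]] + y[["cai"]])
  IpK <- prm[["GpK"]] * (V - EK) / (1 + exp((25 - V) / 5.98))
  IbNa <- prm[["GbNa"]] * (V - ENa)
  IbCa <- prm[["GbCa"]] * (V - ECa)
  list(INa = INa, ICaL = ICaL, Ito = Ito, IKr = IKr, IKs = IKs, IK1 = IK1,
       INaCa = INaCa, INaK = INaK, IpCa = IpCa, IpK = IpK, IbNa = IbNa,
       IbCa = IbCa,
       total = INa + ICaL + Ito + IKr + IKs + IK1 + INaCa + INaK + IpCa +
         IpK + IbNa + IbCa)
}

oracleCalcium <- function(y, cur, prm, istim = 0) {
  F <- prm[["Faraday"]]
  kcasr <- prm[["maxsr"]] - (prm[["maxsr"]] - prm[["minsr"]]) /
    (1 + (prm[["EC"]] / y[["casr"]])^2)
  k1 <- prm[["k1p"]] / kcasr
  k2 <- prm[["k2p"]] * kcasr
  dRR <- prm[["k4"]] * (1 - y[["rr"]]) - k2 * y[["cass"]] * y[["rr"]]
  O <- k1 * y[["cass"]]^2 * y[["rr"]] / (prm[["k3"]] + k1 * y[["cass"]]^2)
  Irel <- prm[["Vrel"]] * O * (y[["casr"]] - y[["cass"]])
  Ileak <- prm[["Vleak"]] * (y[["casr"]] - y[["cai"]])
  Iup <- prm[["Vmaxup"]] / (1 + prm[["Kup"]]^2 / y[["cai"]]^2)
  Ixfer <- prm[["Vxfer"]] * (y[["cass"]] - y[["cai"]])
  bc <- 1 / (1 + prm[["Bufc"]] * prm[["Kbufc"]] / (y[["cai"]] + prm[["Kbufc"]])^2)
  bsr <- 1 / (1 + prm[["Bufsr"]] * prm[["Kbufsr"]] /
                (y[["casr"]] + prm[["Kbufsr"]])^2)
  bss <- 1 / (1 + prm[["Bufss"]] * prm[["Kbufss"]] /
                (y[["cass"]] + prm[["Kbufss"]])^2)
  CAP <- prm[["Cap"]]
  dCai <- bc * (-(cur$IbCa + cur$IpCa - 2 * cur$INaCa) * CAP /
                  (2 * prm[["Vc"]] * F) -
                (Iup - Ileak) * prm[["Vsr"]] / prm[["Vc"]] + Ixfer)
  dCaSR <- bsr * (Iup - Irel - Ileak)
  dCaSS <- bss * (-cur$ICaL * CAP / (2 * prm[["Vss"]] * F) +
                  Irel * prm[["Vsr"]] / prm[["Vss"]] -
                  Ixfer * prm[["Vc"]] / prm[["Vss"]])
  dNai <- -(cur$INa + cur$IbNa + 3 * cur$INaK + 3 * cur$INaCa) * CAP /
    (prm[["Vc"]] * F)
  dKi <- -(istim + cur$IK1 + cur$Ito + cur$IKr + cur$IKs - 2 * cur$INaK +
           cur$IpK) * CAP / (prm[["Vc"]] * F)
  list(dRR = dRR, dCai = dCai, dCaSR = dCaSR, dCaSS = dCaSS,
       dNai = dNai, dKi = dKi)
}

# continuous RHS for deSolve (single cell)
oracleRhs <- function(t, y, parms) {
  prm <- parms$prm
  istim <- if (!is.null(parms$stim) &&
               t >= parms$stim$start &&
               t < parms$stim$start + parms$stim$duration)
    -parms$stim$amplitude else 0
  yl <- as.list(y)
  g <- oracleRates(y[["V"]], prm)
  cur <- oracleCurrents(yl, prm)
  ca <- oracleCalcium(yl, cur, prm, istim)
  fcinf <- 0.6 / (1 + (y[["cass"]] / 0.05)^2) + 0.4
  fctau <- 80 / (1 + (y[["cass"]] / 0.05)^2) + 2
  dy <- c(
    V = -(cur$total + istim),
    m = (g$m_inf - y[["m"]]) / g$m_tau,
    h = (g$h_inf - y[["h"]]) / g$h_tau,
    j = (g$j_inf - y[["j"]]) / g$j_tau,
    xr1 = (g$xr1_inf - y[["xr1"]]) / g$xr1_tau,
    xr2 = (g$xr2_inf - y[["xr2"]]) / g$xr2_tau,
    xs = (g$xs_inf - y[["xs"]]) / g$xs_tau,
    r = (g$r_inf - y[["r"]]) / g$r_tau,
    s = (g$s_inf - y[["s"]]) / g$s_tau,
    d = (g$d_inf - y[["d"]]) / g$d_tau,
    f = (g$f_inf - y[["f"]]) / g$f_tau,
    f2 = (g$f2_inf - y[["f2"]]) / g$f2_tau,
    fcass = (fcinf - y[["fcass"]]) / fctau,
    rr = ca$dRR, cai = ca$dCai, casr = ca$dCaSR, cass = ca$dCaSS,
    nai = ca$dNai, ki = ca$dKi)
  list(dy[tp06StateNames()])
}

# APD90 of a single paced beat from the continuous oracle.  The
# integration is split at the stimulus edges so the adaptive solver
# never steps across the forcing discontinuity.
oracleApd90 <- function(prm, amplitude = 26, stimStart = 10,
                        duration = 450) {
  y0 <- tp06RestingState()
  seg <- function(y, times, stim) {
    deSolve::lsoda(y, times, oracleRhs,
                   parms = list(prm = prm, stim = stim),
                   rtol = 1e-8, atol = 1e-10, maxsteps = 100000)
  }
  s1 <- seg(y0, seq(0, stimStart, by = 0.25), NULL)
  y1 <- s1[nrow(s1), -1]
  s2 <- seg(y1, seq(stimStart, stimStart + 2, by = 0.05),
            list(start = stimStart - 1, duration = 4,
                 amplitude = amplitude))
  y2 <- s2[nrow(s2), -1]
  s3 <- seg(y2, seq(stimStart + 2, duration, by = 0.25), NULL)
  tt <- c(s1[, "time"], s2[-1, "time"], s3[-1, "time"])
  vv <- c(s1[, "V"], s2[-1, "V"], s3[-1, "V"])
  apd(tt, vv)
}

# --- dense-matrix cable oracle (production scheme re-coded in R) -----------

oracleTables <- function(prm, dt, vgrid = seq(-110, 90, by = 0.05)) {
  nm <- c("m", "h", "j", "xr1", "xr2", "xs", "r", "s", "d", "f", "f2")
  tab <- list(v = vgrid)
  rates <- lapply(vgrid, oracleRates, prm = prm)
  for (g in nm) {
    tab[[paste0(g, "_inf")]] <-
      vapply(rates, function(r) r[[paste0(g, "_inf")]], 0)
    tab[[paste0(g, "_rl")]] <-
      vapply(rates, function(r) exp(-dt / r[[paste0(g, "_tau")]]), 0)
  }
  tab
}

oracleInterp <- function(tab, nm, V) {
  u <- (V - tab$v[1]) / (tab$v[2] - tab$v[1])
  u <- pmin(pmax(u, 0), length(tab$v) - 1.001)
  j <- floor(u); w <- u - j
  tab[[nm]][j + 1] * (1 - w) + tab[[nm]][j + 2] * w
}

# n-node cable with no-flux ends, dense Laplacian, same update order as
# the production kernel: RL gate update from V(t), currents from V(t) and
# the updated gates, forward-Euler V and concentrations.
oracleCable <- function(n, prm, ccoup, dt, nsteps, stimNodes = 1:2,
                        stimStart = 5, stimDur = 2, stimAmp = 52,
                        record = NULL, eStride = 1) {
  L <- diag(0, n)
  for (i in seq_len(n - 1)) {
    L[i, i + 1] <- L[i + 1, i] <- 1
  }
  diag(L) <- -rowSums(L)
  y <- sapply(tp06RestingState(), rep, n)  # n x 19
  gates <- c("m", "h", "j", "xr1", "xr2", "xs", "r", "s", "d", "f", "f2")
  tab <- oracleTables(prm, dt)
  RTF <- prm[["Rgas"]] * prm[["Temp"]] / prm[["Faraday"]]
  rec <- matrix(NA_real_, 0, n)
  recT <- numeric(0)
  ENa <- EK <- EKs <- ECa <- rep(0, n)
  for (s in seq_len(nsteps) - 1L) {
    t <- s * dt
    if (s %% eStride == 0) {
      ENa <- RTF * log(prm[["Nao"]] / y[, "nai"])
      EK <- RTF * log(prm[["Ko"]] / y[, "ki"])
      EKs <- RTF * log((prm[["Ko"]] + prm[["pKNa"]] * prm[["Nao"]]) /
                       (y[, "ki"] + prm[["pKNa"]] * y[, "nai"]))
      ECa <- 0.5 * RTF * log(prm[["Cao"]] / y[, "cai"])
    }
    V <- y[, "V"]
    istim <- rep(0, n)
    if (t >= stimStart - 1e-9 && t < stimStart + stimDur - 1e-9)
      istim[stimNodes] <- -stimAmp
    for (g in gates) {
      inf <- oracleInterp(tab, paste0(g, "_inf"), V)
      rl <- oracleInterp(tab, paste0(g, "_rl"), V)
      y[, g] <- inf - (inf - y[, g]) * rl
    }
    fcinf <- 0.6 / (1 + (y[, "cass"] / 0.05)^2) + 0.4
    fctau <- 80 / (1 + (y[, "cass"] / 0.05)^2) + 2
    y[, "fcass"] <- y[, "fcass"] + dt * (fcinf - y[, "fcass"]) / fctau
    INa <- prm[["GNa"]] * y[, "m"]^3 * y[, "h"] * y[, "j"] * (V - ENa)
    x <- 2 * (V - 15) / RTF
    ICaL <- prm[["GCaL"]] * y[, "d"] * y[, "f"] * y[, "f2"] * y[, "fcass"] *
      4 * (V - 15) * prm[["Faraday"]] / RTF *
      (0.25 * y[, "cass"] * exp(x) - prm[["Cao"]]) / expm1(x)
    Ito <- prm[["Gto"]] * y[, "r"] * y[, "s"] * (V - EK)
    IKr <- prm[["GKr"]] * sqrt(prm[["Ko"]] / 5.4) * y[, "xr1"] *
      y[, "xr2"] * (V - EK)
    IKs <- prm[["GKs"]] * y[, "xs"]^2 * (V - EKs)
    aK1 <- 0.1 / (1 + exp(0.06 * (V - EK - 200)))
    bK1 <- (3 * exp(2e-4 * (V - EK + 100)) + exp(0.1 * (V - EK - 10))) /
      (1 + exp(-0.5 * (V - EK)))
    IK1 <- prm[["GK1"]] * aK1 / (aK1 + bK1) * (V - EK)
    INaCa <- prm[["kNaCa"]] *
      (exp(prm[["gamma"]] * V / RTF) * y[, "nai"]^3 * prm[["Cao"]] -
       exp((prm[["gamma"]] - 1) * V / RTF) * prm[["Nao"]]^3 *
         y[, "cai"] * 2.5) /
      ((prm[["KmNai"]]^3 + prm[["Nao"]]^3) * (prm[["KmCa"]] + prm[["Cao"]]) *
       (1 + prm[["ksat"]] * exp((prm[["gamma"]] - 1) * V / RTF)))
    INaK <- prm[["PNaK"]] * prm[["Ko"]] * y[, "nai"] /
      ((prm[["Ko"]] + prm[["KmK"]]) * (y[, "nai"] + prm[["KmNa"]])) /
      (1 + 0.1245 * exp(-0.1 * V / RTF) + 0.0353 * exp(-V / RTF))
    IpCa <- prm[["GpCa"]] * y[, "cai"] / (prm[["KpCa"]] + y[, "cai"])
    IpK <- prm[["GpK"]] * (V - EK) / (1 + exp((25 - V) / 5.98))
    IbNa <- prm[["GbNa"]] * (V - ENa)
    IbCa <- prm[["GbCa"]] * (V - ECa)
    iion <- INa + ICaL + Ito + IKr + IKs + IK1 + INaCa + INaK + IpCa +
      IpK + IbNa + IbCa
    kcasr <- prm[["maxsr"]] - (prm[["maxsr"]] - prm[["minsr"]]) /
      (1 + (prm[["EC"]] / y[, "casr"])^2)
    k1 <- prm[["k1p"]] / kcasr
    k2 <- prm[["k2p"]] * kcasr
    rrOld <- y[, "rr"]
    y[, "rr"] <- rrOld + dt * (prm[["k4"]] * (1 - rrOld) -
                               k2 * y[, "cass"] * rrOld)
    O <- k1 * y[, "cass"]^2 * rrOld / (prm[["k3"]] + k1 * y[, "cass"]^2)
    Irel <- prm[["Vrel"]] * O * (y[, "casr"] - y[, "cass"])
    Ileak <- prm[["Vleak"]] * (y[, "casr"] - y[, "cai"])
    Iup <- prm[["Vmaxup"]] / (1 + prm[["Kup"]]^2 / y[, "cai"]^2)
    Ixfer <- prm[["Vxfer"]] * (y[, "cass"] - y[, "cai"])
    bc <- 1 / (1 + prm[["Bufc"]] * prm[["Kbufc"]] /
                 (y[, "cai"] + prm[["Kbufc"]])^2)
    bsr <- 1 / (1 + prm[["Bufsr"]] * prm[["Kbufsr"]] /
                  (y[, "casr"] + prm[["Kbufsr"]])^2)
    bss <- 1 / (1 + prm[["Bufss"]] * prm[["Kbufss"]] /
                  (y[, "cass"] + prm[["Kbufss"]])^2)
    CAP <- prm[["Cap"]]; F <- prm[["Faraday"]]
    y[, "cai"] <- y[, "cai"] + dt * bc *
      (-(IbCa + IpCa - 2 * INaCa) * CAP / (2 * prm[["Vc"]] * F) -
       (Iup - Ileak) * prm[["Vsr"]] / prm[["Vc"]] + Ixfer)
    y[, "casr"] <- y[, "casr"] + dt * bsr * (Iup - Irel - Ileak)
    y[, "cass"] <- y[, "cass"] + dt * bss *
      (-ICaL * CAP / (2 * prm[["Vss"]] * F) +
       Irel * prm[["Vsr"]] / prm[["Vss"]] - Ixfer * prm[["Vc"]] / prm[["Vss"]])
    y[, "nai"] <- y[, "nai"] + dt *
      (-(INa + IbNa + 3 * INaK + 3 * INaCa) * CAP / (prm[["Vc"]] * F))
    y[, "ki"] <- y[, "ki"] + dt *
      (-(istim + IK1 + Ito + IKr + IKs - 2 * INaK + IpK) * CAP /
         (prm[["Vc"]] * F))
    y[, "V"] <- V + dt * (ccoup * as.vector(L %*% V) - iion - istim)
    if (!is.null(record) && (s + 1) %% record == 0) {
      rec <- rbind(rec, y[, "V"])
      recT <- c(recT, (s + 1) * dt)
    }
  }
  list(V = y[, "V"], state = y, trace = rec, traceTimes = recT)
}

# --- brute-force winding-number detector -----------------------------------

oracleWinding <- function(v1, v0, obstacle = NULL, vstar = -40) {
  nr <- nrow(v1); nc <- ncol(v1)
  if (is.null(obstacle)) obstacle <- matrix(FALSE, nr, nc)
  th <- atan2(v1 - vstar, v0 - vstar)
  wrap <- function(d) (d + pi) %% (2 * pi) - pi
  out <- NULL
  for (r in seq_len(nr - 1)) {
    for (c in seq_len(nc - 1)) {
      if (obstacle[r, c] || obstacle[r + 1, c] || obstacle[r + 1, c + 1] ||
          obstacle[r, c + 1]) next
      w <- wrap(th[r + 1, c] - th[r, c]) +
        wrap(th[r + 1, c + 1] - th[r + 1, c]) +
        wrap(th[r, c + 1] - th[r + 1, c + 1]) +
        wrap(th[r, c] - th[r, c + 1])
      if (abs(w) > pi)
        out <- rbind(out, data.frame(row = r + 0.5, col = c + 0.5,
                                     charge = sign(w)))
    }
  }
  if (is.null(out)) data.frame(row = numeric(0), col = numeric(0),
                               charge = numeric(0))
  else out
}

# --- direct-summation pseudo-ECG oracle ------------------------------------

oracleEcg <- function(vm, obstacle, dx, electrode, D) {
  nr <- nrow(vm); nc <- ncol(vm)
  acc <- 0
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      if (obstacle[r, c]) next
      gx <- gy <- 0
      up <- r > 1 && !obstacle[r - 1, c]
      dn <- r < nr && !obstacle[r + 1, c]
      if (up && dn) gx <- (vm[r + 1, c] - vm[r - 1, c]) / (2 * dx)
      else if (dn) gx <- (vm[r + 1, c] - vm[r, c]) / dx
      else if (up) gx <- (vm[r, c] - vm[r - 1, c]) / dx
      lf <- c > 1 && !obstacle[r, c - 1]
      rt <- c < nc && !obstacle[r, c + 1]
      if (lf && rt) gy <- (vm[r, c + 1] - vm[r, c - 1]) / (2 * dx)
      else if (rt) gy <- (vm[r, c + 1] - vm[r, c]) / dx
      else if (lf) gy <- (vm[r, c] - vm[r, c - 1]) / dx
      rx <- electrode[1] - (r - 1) * dx
      ry <- electrode[2] - (c - 1) * dx
      rz <- electrode[3]
      rmag <- sqrt(rx^2 + ry^2 + rz^2)
      acc <- acc + D * (rx * gx + ry * gy) / rmag^3 * dx^2
    }
  }
  acc
}

# a synthetic Archimedean-spiral phase pair for detector tests
spiralFrames <- function(nr = 40, nc = 40, center = c(20.5, 20.5),
                         pitch = 0.35, chirality = 1, vstar = -40,
                         amp = 40) {
  rr <- outer(seq_len(nr) - center[1], rep(1, nc))
  cc <- outer(rep(1, nr), seq_len(nc) - center[2])
  phi <- atan2(cc, rr) * chirality + pitch * sqrt(rr^2 + cc^2)
  list(v1 = vstar + amp * sin(phi), v0 = vstar + amp * cos(phi))
}
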