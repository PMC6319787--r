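# Stimulation protocols: planar-wave conduction velocity, conduction
# block sweeps, and S1S2 rotor initiation.

#' Planar conduction velocity on a strip
#'
#' Paces one edge of a thin strip at the given cycle length, lets the
#' requested number of conditioning beats pass, and measures the
#' conduction velocity of the next beat from the activation-time
#' difference between two probe rows >= 2 cm apart (activation = first
#' upward crossing of -20 mV, resolved at the integration step).  With a
#' nonzero uniform fibrosis level the strip carries one obstacle texture
#' per seed and the velocity is summarized over seeds; a seed whose wave
#' never reaches the distal probe row is reported as blocked.
#'
#' @param level Uniform fibrosis percentage of the strip.
#' @param cl Pacing cycle length (ms).
#' @param seeds Texture seeds (ignored at level 0, where one noiseless
#'   run suffices).
#' @param dims Strip dimensions (rows, cols); the wave runs along rows.
#' @param probeRows Two rows used for timing (default 120 and 280,
#'   i.e. 4 cm apart at 250 um spacing).
#' @param conditioningBeats Tissue-level beats delivered before the
#'   measured beat.
#' @param pacedInit Start every node from the single-cell state paced
#'   twice at `cl` (so the measured beat sees 1 Hz diastolic history
#'   even with few tissue-level conditioning beats).
#' @param config Base [SimConfig-class] template; `duration` is ignored.
#' @param remodeling Apply ionic remodeling inside the fibrotic strip.
#' @return List with `cv` (mean over seeds, cm/s; `NA` if all blocked),
#'   `sd`, `perSeed` (data.frame of seed, cv, blocked), `blockedFraction`.
#' @export
measureCV <- function(level = 0, cl = 1000, seeds = 1:10,
                      dims = c(400, 24), probeRows = c(120, 280),
                      conditioningBeats = 2, pacedInit = FALSE,
                      config = simConfig(duration = 0,
                                         params = tp06Params("epi")),
                      remodeling = FALSE) {
  stopifnot(level >= 0, level <= 100, diff(probeRows) * 0.025 >= 2)
  if (level == 0) seeds <- seeds[1]
  if (level > 0 && dims[2] < 48) dims[2] <- 48  # texture needs width
  spacingCm <- 0.025
  amp <- 2 * diastolicThreshold(config@params)
  init0 <- if (pacedInit) pacedState(config@params, cl = cl) else "rest"
  one <- function(seed) {
    map <- matrix(level, dims[1], dims[2])
    grid <- tissueGrid(map, seed = seed, spacing = spacingCm)
    # the paced edge stays fibrosis-free so the stimulus always captures
    grid@fibrosis@pct[1:3, ] <- 0
    grid@obstacles@mask[1:3, ] <- FALSE
    cond <- simConfig(duration = conditioningBeats * cl, dt = config@dt,
                      gGap = config@gGap, cmNode = config@cmNode,
                      params = config@params, remodeling = remodeling,
                      frameStride = 0, probeStride = 1, seed = seed)
    stims <- lapply(cl * (seq_len(conditioningBeats) - 1), function(t0)
      edgeStimulus(dims, rows = 1:3, start = t0, amplitude = amp))
    st <- if (conditioningBeats > 0)
      finalState(runTissue(grid, cond, stims, init = init0)) else init0
    t0 <- conditioningBeats * cl
    meas <- simConfig(duration = max(800, dims[1] * spacingCm / 0.02),
                      dt = config@dt, gGap = config@gGap,
                      cmNode = config@cmNode, params = config@params,
                      remodeling = remodeling, frameStride = 0,
                      probeStride = 1, seed = seed)
    rec <- runTissue(grid, meas,
                     list(edgeStimulus(dims, rows = 1:3, start = t0,
                                       amplitude = amp)),
                     init = st, t0 = t0,
                     stopOnActivation = cbind(dims[1] - 2, seq_len(dims[2])))
    at <- rec@actTime
    a1 <- median(at[probeRows[1], ], na.rm = TRUE)
    a2 <- median(at[probeRows[2], ], na.rm = TRUE)
    if (!is.finite(a1) || !is.finite(a2) || a2 <= a1)
      return(c(cv = NA_real_, blocked = 1))
    c(cv = diff(probeRows) * spacingCm / (a2 - a1) * 1000, blocked = 0)
  }
  res <- t(vapply(seeds, one, c(cv = 0, blocked = 0)))
  per <- data.frame(seed = seeds, cv = res[, "cv"],
                    blocked = res[, "blocked"] == 1)
  list(cv = if (all(per$blocked)) NA_real_ else mean(per$cv, na.rm = TRUE),
       sd = sd(per$cv, na.rm = TRUE), perSeed = per,
       blockedFraction = mean(per$blocked))
}

#' Conduction-block sweep over uniform fibrosis levels
#'
#' Sends a single planar wave at a patch whose central band carries
#' uniform diffuse fibrosis, for every combination of level and texture
#' seed, and records whether the wave crosses the band.  The block
#' threshold is the lowest level at which no seed lets the wave through
#' (above roughly 41% fibrosis the myocyte lattice stops percolating and
#' the band behaves as inexcitable scar).
#'
#' @param levels Fibrosis percentages to sweep (ascending).
#' @param seeds Texture seeds per level.
#' @param dims Patch dimensions (rows, cols).
#' @param bandRows Rows forming the fibrotic band.
#' @param config Base [SimConfig-class] template.
#' @param lazy Evaluate the sweep lazily: within a level, stop running
#'   seeds once one wave crosses (the level is then not fully blocked);
#'   across levels, stop at the first fully blocked level.  This leaves
#'   the estimate — the lowest level at which no seed crosses —
#'   unchanged while skipping runs that cannot affect it.
#' @return List with `threshold` (lowest all-blocked level, `NA` if none),
#'   `table` (data.frame level, seed, crossed).
#' @export
blockThreshold <- function(levels = 35:48, seeds = 1:10,
                           dims = c(200, 100), bandRows = 51:150,
                           config = simConfig(duration = 0,
                                              params = tp06Params("epi")),
                           lazy = TRUE) {
  amp <- 2 * diastolicThreshold(config@params)
  distalRow <- max(bandRows) + 10
  oneRun <- function(level, seed) {
    map <- matrix(0, dims[1], dims[2])
    map[bandRows, ] <- level
    grid <- tissueGrid(map, seed = seed)
    cfg <- simConfig(duration = 600, dt = config@dt, gGap = config@gGap,
                     cmNode = config@cmNode, params = config@params,
                     frameStride = 0, probeStride = 1, seed = seed)
    rec <- runTissue(grid, cfg,
                     list(edgeStimulus(dims, rows = 1:3, amplitude = amp)),
                     stopAllQuiet = TRUE, quietAfter = 50,
                     stopOnActivation = cbind(distalRow, seq_len(dims[2])))
    any(is.finite(rec@actTime[distalRow:dims[1], ]))
  }
  tab <- data.frame(level = numeric(0), seed = numeric(0),
                    crossed = logical(0))
  threshold <- NA_real_
  for (lv in sort(levels)) {
    blockedAll <- TRUE
    for (sd in seeds) {
      cr <- oneRun(lv, sd)
      tab <- rbind(tab, data.frame(level = lv, seed = sd, crossed = cr))
      if (cr) {
        blockedAll <- FALSE
        if (lazy) break
      }
    }
    if (blockedAll) {
      if (is.na(threshold)) threshold <- lv
      if (lazy) break
    }
  }
  list(threshold = threshold, table = tab)
}

#' Initiate a rotor with a cross-field S1S2 protocol
#'
#' Delivers a planar S1 along the top rows, waits for the repolarization
#' tail (the falling crossing of `wavebackLevel`) to reach the intended
#' tip position, then delivers an S2 over the half-plane of columns left
#' of the tip.  The broken S2 wavefront curls into a single rotor whose
#' phase singularity is verified to lie within 1 cm of the intended
#' position; zero or multiple singularities raise a protocol-failure
#' error carrying the diagnostic frame.
#'
#' @param grid A [TissueGrid-class]; the neighborhood of the intended tip
#'   must be obstacle-free.
#' @param config A [SimConfig-class] template (its duration is ignored).
#' @param spec An [S1S2Spec-class].
#' @param settle Time (ms) simulated after S2 before the singularity
#'   check.
#' @return List with `state` (tissue state holding one rotor), `tip`
#'   (detected singularity row/col/charge), `s2Time` (ms), `recording`
#'   (the post-S2 settling recording).
#' @export
initiateRotor <- function(grid, config, spec, settle = 400) {
  d <- gridDim(grid)
  tipIdx <- cbind(round(spec@tip[1]), round(spec@tip[2]))
  amp <- 2 * diastolicThreshold(config@params)
  base <- function(duration, frameStride = 0)
    simConfig(duration = duration, dt = config@dt, gGap = config@gGap,
              cmNode = config@cmNode, params = config@params,
              remodeling = config@remodeling, frameStride = frameStride,
              probeStride = 1, seed = config@seed)
  # S1 train, then wait for the last beat's wavefront at the tip
  s1 <- lapply(spec@s1Times, function(t0)
    edgeStimulus(d, rows = spec@s1Rows, start = t0, amplitude = amp))
  tLast <- max(spec@s1Times)
  state <- "rest"; t <- 0
  if (tLast > 0) {
    pre <- runTissue(grid, base(tLast), s1)
    state <- finalState(pre); t <- tLast
  }
  travel <- runTissue(grid,
                      base(spec@tip[1] * spacing(grid) / 0.02 + 250),
                      s1, init = state, t0 = t,
                      stopOnActivation = tipIdx)
  if (travel@stopReason != "target_activated")
    stop("S1 wave never reached the intended tip position")
  t <- travel@stopTime
  state <- finalState(travel)
  # jump over most of the plateau, then creep in short hops until the
  # waveback passes the tip
  skip <- runTissue(grid, base(120), init = state, t0 = t)
  state <- finalState(skip); t <- t + 120
  tipNode <- rcToIdx(tipIdx, d[1])
  repeat {
    hop <- runTissue(grid, base(2), init = state, t0 = t)
    vprev <- state[tipNode, 1]; state <- finalState(hop); t <- t + 2
    if (vprev >= spec@wavebackLevel && state[tipNode, 1] < spec@wavebackLevel)
      break
    if (t > travel@stopTime + 600)
      stop("S1 waveback never crossed the intended tip position")
  }
  # S2 half-plane, then let the spiral form
  s2mask <- matrix(FALSE, d[1], d[2])
  s2mask[, spec@s2Cols] <- TRUE
  s2 <- stimulusSpec(s2mask, start = t, duration = 2, amplitude = amp)
  post <- runTissue(grid, base(settle, frameStride = 10), list(s2),
                    init = state, t0 = t)
  # transient wavebreak pairs flicker around a meandering tip; judge the
  # rotor count by the cleanest of the last few settle frames
  ft <- frameTimes(post)
  checks <- tail(ft, 4)
  psList <- lapply(checks, function(tt) detectSingularities(post, tt))
  counts <- vapply(psList, nrow, 0L)
  best <- which(counts == 1)
  if (!length(best)) {
    err <- simpleError(sprintf(
      "S1S2 protocol produced %s phase singularities (expected 1)",
      paste(counts, collapse = "/")))
    err$frame <- voltageFrame(post, max(ft))
    stop(err)
  }
  ps <- psList[[best[length(best)]]]
  distCm <- sqrt(sum((c(ps$row, ps$col) - spec@tip)^2)) * spacing(grid)
  if (distCm > 1)
    warning(sprintf("rotor tip %.2f cm from intended position", distCm))
  list(state = finalState(post), tip = ps, s2Time = t,
       endTime = t + settle, recording = post)
}

#' Rotation period of a free rotor in homogeneous tissue
#'
#' Initiates a rotor by the cross-field S1S2 protocol in an
#' obstacle-free sheet, lets the transients pass, and measures the
#' median inter-activation interval at a probe ring around the core
#' (plus far-field probes) over the final `measureWindow` of the run.
#'
#' @param dims Sheet dimensions (rows, cols).
#' @param duration Total simulated time (ms) including initiation.
#' @param measureWindow Window (ms) at the end of the run over which the
#'   period is taken.
#' @param params TP06 parameter vector.
#' @param cmNode Node capacitance (pF).
#' @param tip Intended tip position; default = sheet center.
#' @return List with `period` (ms), `recording`, `tipTrack`.
#' @export
freeRotorPeriod <- function(dims = c(240, 240), duration = 2200,
                            measureWindow = 1000, params = tp06Params(),
                            cmNode = NULL, tip = NULL,
                            wavebackLevel = -60) {
  grid <- tissueGrid(matrix(0, dims[1], dims[2]))
  tip <- tip %||% c(round(dims[1] * 0.5), round(dims[2] * 0.5))
  cfg <- simConfig(duration = duration, params = params, cmNode = cmNode,
                   probes = rbind(probeRing(tip, 1.5, 12, grid),
                                  probeRing(tip, 2.5, 4, grid)))
  ini <- initiateRotor(grid, cfg,
                       s1s2Spec(tip, wavebackLevel = wavebackLevel))
  main <- simConfig(duration = duration - ini$endTime, params = params,
                    cmNode = cmNode, probes = cfg@probes, seed = cfg@seed)
  rec <- runTissue(grid, main, list(), init = ini$state, t0 = ini$endTime)
  list(period = measurePeriod(rec, windowEnd = duration,
                              window = measureWindow),
       recording = rec, tipTrack = trackSingularities(rec),
       initiation = ini)
}

#' Probe ring around a point
#'
#' Places `n` probes evenly on a circle, clipped to the grid and moved
#' off obstacle nodes (nearest myocyte within 2 nodes; probes with no
#' myocyte nearby are dropped).
#'
#' @param center (row, col) center.
#' @param radiusCm Circle radius in cm.
#' @param n Number of probes.
#' @param grid The [TissueGrid-class] to clip against.
#' @return Two-column matrix (row, col).
#' @export
probeRing <- function(center, radiusCm, n = 16, grid) {
  d <- gridDim(grid); dx <- spacing(grid)
  obst <- obstacleMask(grid)
  ang <- 2 * pi * (seq_len(n) - 1) / n
  pts <- cbind(round(center[1] + radiusCm / dx * sin(ang)),
               round(center[2] + radiusCm / dx * cos(ang)))
  keep <- matrix(numeric(0), 0, 2)
  for (k in seq_len(n)) {
    r <- pts[k, 1]; c <- pts[k, 2]
    if (r < 1 || r > d[1] || c < 1 || c > d[2]) next
    found <- FALSE
    for (dr in 0:2) {
      cand <- expand.grid(r = max(1, r - dr):min(d[1], r + dr),
                          c = max(1, c - dr):min(d[2], c + dr))
      ok <- !obst[as.matrix(cand)]
      if (any(ok)) {
        keep <- rbind(keep, as.matrix(cand[which(ok)[1], ]))
        found <- TRUE; break
      }
    }
  }
  unname(keep)
}
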