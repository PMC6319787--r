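# Single-cell runs, action-potential metrics and the diastolic-threshold
# search used to size tissue stimuli.

#' Run a single TP06 cell
#'
#' Integrates one isolated myocyte (a 1 x 1 grid, so exactly the tissue
#' integrator with zero coupling) with stimuli delivered at the given
#' times.
#'
#' @param params TP06 parameter vector.
#' @param duration Total time (ms).
#' @param stimTimes Stimulus onset times (ms).
#' @param amplitude Stimulus amplitude (pA/pF, depolarizing).
#' @param stimDuration Pulse length (ms).
#' @param dt Time step (ms).
#' @param init Initial state vector (default: resting state).
#' @param probeStride Sampling interval of the returned trace (ms).
#' @return List with `times`, `V` (sampled trace) and `finalState`.
#' @examples
#' ap <- singleCellRun(duration = 500, stimTimes = 10)
#' max(ap$V) > 0   # overshoot
#' @export
singleCellRun <- function(params = tp06Params(), duration = 1000,
                          stimTimes = numeric(0), amplitude = 52,
                          stimDuration = 2, dt = 0.02,
                          init = tp06RestingState(), probeStride = 0.1) {
  grid <- tissueGrid(matrix(0, 1, 1))
  cfg <- simConfig(duration = duration, dt = dt, params = params,
                   probeStride = min(probeStride, 1), frameStride = 0,
                   probes = cbind(1, 1), eStride = 1L)
  stim <- lapply(stimTimes, function(t0)
    stimulusSpec(matrix(TRUE, 1, 1), start = t0, duration = stimDuration,
                 amplitude = amplitude))
  rec <- runTissue(grid, cfg, stim, init = init)
  list(times = probeTimes(rec), V = as.vector(probeTraces(rec)),
       finalState = finalState(rec)[1, , drop = TRUE],
       recording = rec)
}

#' Action potential duration at a repolarization fraction
#'
#' APD is measured from the maximum upstroke velocity to the crossing of
#' the repolarization level V_rest + (1 - frac) * (V_peak - V_rest),
#' i.e. `frac = 0.9` gives APD90.
#'
#' @param times,V Sampled action-potential trace.
#' @param frac Repolarization fraction (default 0.9).
#' @return APD in ms (`NA` when no action potential is present).
#' @export
apd <- function(times, V, frac = 0.9) {
  dV <- diff(V) / diff(times)
  up <- which.max(dV)
  if (dV[up] < 1) return(NA_real_)   # no upstroke
  vrest <- min(V[seq_len(up)])       # diastolic level before the upstroke
  vpeak <- max(V[up:length(V)])
  level <- vrest + (1 - frac) * (vpeak - vrest)
  post <- seq(which.max(V), length(V))
  below <- post[which(V[post] <= level)]
  if (!length(below)) return(NA_real_)
  icross <- below[1]
  # linear interpolation of the crossing
  if (icross > 1 && V[icross - 1] > level) {
    t0 <- times[icross - 1] + (V[icross - 1] - level) /
      (V[icross - 1] - V[icross]) * (times[icross] - times[icross - 1])
  } else t0 <- times[icross]
  t0 - times[up]
}

#' Diastolic stimulation threshold of a parameter set
#'
#' Finds, by bisection, the smallest 2 ms current pulse that elicits an
#' action potential (overshoot above 0 mV) from rest, and caches the
#' result per parameter-set hash.  Tissue protocols stimulate at twice
#' this threshold.
#'
#' @param params TP06 parameter vector.
#' @param stimDuration Pulse length (ms).
#' @param tol Bisection tolerance (pA/pF).
#' @return Threshold amplitude in pA/pF.
#' @export
diastolicThreshold <- function(params = tp06Params(), stimDuration = 2,
                               tol = 0.5) {
  key <- paste0("thr_", raHash(list(params, stimDuration)))
  if (!is.null(.ra_cache[[key]])) return(.ra_cache[[key]])
  fires <- function(amp) {
    tr <- singleCellRun(params, duration = 60, stimTimes = 5,
                        amplitude = amp, stimDuration = stimDuration)
    max(tr$V) > 0
  }
  lo <- 0; hi <- 16
  while (!fires(hi)) {
    hi <- hi * 2
    if (hi > 600) stop("cell appears inexcitable")
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (fires(mid)) hi <- mid else lo <- mid
  }
  .ra_cache[[key]] <- hi
  hi
}

#' Paced steady-ish single-cell state
#'
#' Applies `nBeats` stimuli at cycle length `cl` and returns the state
#' just before the next beat, for use as a conditioned initial state.
#'
#' @param params TP06 parameter vector.
#' @param cl Cycle length (ms).
#' @param nBeats Number of conditioning beats.
#' @param amplitude Stimulus amplitude (pA/pF).
#' @param dt Time step (ms).
#' @return Named state vector.
#' @export
pacedState <- function(params = tp06Params(), cl = 1000, nBeats = 2,
                       amplitude = 52, dt = 0.02) {
  run <- singleCellRun(params, duration = cl * nBeats,
                       stimTimes = cl * (seq_len(nBeats) - 1),
                       amplitude = amplitude, dt = dt)
  st <- run$finalState
  names(st) <- tp06StateNames()
  st
}
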