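# Tissue simulation driver around the compiled integrator.

# Default node capacitance (pF).  With g_gap = 103.6 nS and dx = 250 um
# this coupling strength yields a planar conduction velocity of 72 cm/s
# at CL 1000 ms (see the calibration note in the methods vignette).
ra_default_cm_node <- 43.3512
# ... and for the reduced-excitability re-entry variant ("spiral"),
# whose stronger coupling compensates the lower sodium conductance.
ra_spiral_cm_node <- 27.745

#' Build the gap-junction connectivity of a tissue grid
#'
#' Couples every myocyte to its 4 von Neumann neighbors that are also
#' myocytes.  Edges crossing the domain boundary or touching an obstacle
#' are uncoupled, which implements no-flux boundary conditions.  Returned
#' as a per-node neighbor count plus the full neighbor index table, which
#' is what the property tests inspect; the integrator rebuilds the same
#' structure internally.
#'
#' @param grid A [TissueGrid-class] (or logical obstacle matrix).
#' @return List with `count` (matrix of per-node coupling counts, `NA`
#'   on obstacles) and `neighbors` (n x 4 matrix of 1-based node indices,
#'   `NA` where uncoupled; columns up, down, left, right).
#' @export
buildConnectivity <- function(grid) {
  obst <- if (is.matrix(grid)) grid else obstacleMask(grid)
  nr <- nrow(obst); nc <- ncol(obst)
  idx <- matrix(seq_len(nr * nc), nr, nc)
  shift <- function(dr, dc) {
    m <- matrix(NA_integer_, nr, nc)
    rs <- seq_len(nr) + dr; cs <- seq_len(nc) + dc
    ok_r <- rs >= 1 & rs <= nr; ok_c <- cs >= 1 & cs <= nc
    m[ok_r, ok_c] <- idx[rs[ok_r], cs[ok_c]]
    m[obst] <- NA_integer_            # obstacle has no couplings
    sel <- !is.na(m)
    sel[sel] <- obst[m[sel]]          # drop edges into obstacles
    m[sel] <- NA_integer_
    m
  }
  nb <- cbind(up = as.vector(shift(-1, 0)), down = as.vector(shift(1, 0)),
              left = as.vector(shift(0, -1)), right = as.vector(shift(0, 1)))
  count <- matrix(rowSums(!is.na(nb)), nr, nc)
  count[obst] <- NA_integer_
  list(count = count, neighbors = nb)
}

# per-node conductance vectors, applying remodeling where requested
nodeConductances <- function(grid, config) {
  p <- config@params
  f <- as.vector(fibrosisPct(grid))
  if (isTRUE(config@remodeling)) {
    s <- remodelingFactors(f)
    list(gna = p[["GNa"]] * s[, "sNa"], gkr = p[["GKr"]] * s[, "sKr"],
         gks = p[["GKs"]] * s[, "sKs"])
  } else {
    n <- length(f)
    list(gna = rep(p[["GNa"]], n), gkr = rep(p[["GKr"]], n),
         gks = rep(p[["GKs"]], n))
  }
}

maskToIdx0 <- function(mask, obst) {
  which(as.vector(mask) & !as.vector(obst)) - 1L
}

rcToIdx <- function(rc, nr) (rc[, 2] - 1L) * nr + rc[, 1]

ecgWeights <- function(grid, electrode, diffusion) {
  d <- gridDim(grid); dx <- spacing(grid)
  x <- (seq_len(d[1]) - 1) * dx; y <- (seq_len(d[2]) - 1) * dx
  rx <- outer(electrode[1] - x, rep(1, d[2]))
  ry <- outer(rep(1, d[1]), electrode[2] - y)
  rz <- electrode[3]
  r3 <- (rx^2 + ry^2 + rz^2)^1.5
  if (min(sqrt(rx^2 + ry^2 + rz^2)) < 1)
    stop("electrode must be at least 1 cm from the tissue")
  list(wx = as.vector(diffusion * rx / r3) * dx^2,
       wy = as.vector(diffusion * ry / r3) * dx^2)
}

#' Run a tissue simulation
#'
#' Advances the discrete monodomain model on a [TissueGrid-class] with
#' forward-Euler voltage updates and Rush-Larsen gate updates, delivering
#' the given stimuli and recording probe traces, voltage snapshots, first
#' activation times and (optionally) an online pseudo-ECG.  The run is
#' fully deterministic given grid, config, stimuli and initial state.
#'
#' @param grid A [TissueGrid-class].
#' @param config A [SimConfig-class].
#' @param stimuli List of [StimulusSpec-class] objects (may be empty).
#' @param init Initial state: `"rest"`, a 19-element named state vector
#'   applied uniformly, or a full n x 19 state matrix (e.g. the
#'   `finalState` of a previous recording, for continuation runs).
#' @param t0 Start time (ms) assigned to the initial frame.
#' @param stopAllQuiet Stop early once every myocyte is below -20 mV
#'   (checked every 10 ms, only after `quietAfter`).
#' @param quietAfter Earliest time (ms) the all-quiet exit may fire.
#' @param stopOnActivation Optional (row, col) matrix; stop once any of
#'   these nodes activates.
#' @param zeroIon Replace the ionic current by 0 (diffusion-only test
#'   mode).
#' @return A [SimRecording-class].
#' @export
runTissue <- function(grid, config, stimuli = list(), init = "rest",
                      t0 = 0, stopAllQuiet = FALSE, quietAfter = 0,
                      stopOnActivation = NULL, zeroIon = FALSE) {
  stopifnot(is(grid, "TissueGrid"), is(config, "SimConfig"))
  validObject(grid); validObject(config)
  d <- gridDim(grid); n <- prod(d)
  obst <- obstacleMask(grid)
  if (identical(init, "rest")) {
    rest <- tp06RestingState()
    state <- matrix(rep(rest, each = n), n, 19)
  } else if (is.numeric(init) && is.null(dim(init))) {
    state <- matrix(rep(init[tp06StateNames()], each = n), n, 19)
  } else {
    state <- init
    stopifnot(is.matrix(state), nrow(state) == n, ncol(state) == 19)
  }
  g <- nodeConductances(grid, config)
  sidx <- lapply(stimuli, function(s) {
    validObject(s)
    if (!identical(dim(s@mask), d)) stop("stimulus mask dimension mismatch")
    maskToIdx0(s@mask, obst)
  })
  dt <- config@dt
  nsteps <- max(0L, as.integer(round(config@duration / dt)))
  probes0 <- if (nrow(config@probes))
    as.integer(rcToIdx(config@probes, d[1]) - 1L) else integer(0)
  ew <- list(wx = numeric(0), wy = numeric(0))
  if (length(config@ecgElectrode) == 3) {
    D <- config@gGap / config@cmNode * spacing(grid)^2
    ew <- ecgWeights(grid, config@ecgElectrode, D)
  }
  stopAct0 <- if (!is.null(stopOnActivation))
    as.integer(rcToIdx(stopOnActivation, d[1]) - 1L) else integer(0)
  res <- .sim_run_cpp(
    state, d[1], d[2], as.vector(obst), g$gna, g$gkr, g$gks,
    config@params, dt, nsteps, t0,
    config@gGap / config@cmNode,
    sidx,
    vapply(stimuli, function(s) s@start, 0),
    vapply(stimuli, function(s) s@duration, 0),
    vapply(stimuli, function(s) -abs(s@amplitude), 0),
    probes0, as.integer(round(config@probeStride / dt)),
    if (config@frameStride > 0) as.integer(round(config@frameStride / dt)) else 0L,
    ew$wx, ew$wy,
    if (length(ew$wx)) as.integer(round(config@probeStride / dt)) else 0L,
    -20, config@eStride,
    stopAllQuiet, quietAfter, stopAct0, zeroIon, spacing(grid))
  nrec <- res$n_recorded
  frames <- res$frames
  ftimes <- res$frame_t
  if (length(ftimes)) {
    frames <- frames[, seq_len(nrec[["frames"]]), drop = FALSE]
    ftimes <- ftimes[seq_len(nrec[["frames"]])]
    frames[as.vector(obst), ] <- NA_real_
  }
  probes <- res$probes
  ptimes <- res$probe_t
  if (length(ptimes)) {
    probes <- probes[seq_len(nrec[["probes"]]), , drop = FALSE]
    ptimes <- ptimes[seq_len(nrec[["probes"]])]
  }
  ecg <- res$ecg; etimes <- res$ecg_t
  if (length(etimes)) {
    ecg <- ecg[seq_len(nrec[["ecg"]])]
    etimes <- etimes[seq_len(nrec[["ecg"]])]
  }
  new("SimRecording",
      frames = frames, frameTimes = as.numeric(ftimes),
      probes = probes, probeTimes = as.numeric(ptimes),
      probeIndex = config@probes,
      ecg = as.numeric(ecg), ecgTimes = as.numeric(etimes),
      actTime = matrix(res$act_time, d[1], d[2]),
      finalState = res$state, grid = grid, config = config,
      configHash = raHash(list(fibrosisPct(grid), obstacleMask(grid),
                               config@params, config@dt, config@duration,
                               config@gGap, config@cmNode,
                               config@remodeling, lapply(stimuli, slotList))),
      stopReason = res$stop_reason,
      stopTime = as.numeric(res$stop_time))
}

slotList <- function(s) list(s@mask, s@start, s@duration, s@amplitude)

#' Edge stimulus helper
#'
#' Builds a planar stimulus over a block of rows or columns.
#'
#' @param dims Grid dimensions (rows, cols).
#' @param rows,cols Rows/columns covered (defaults: all).
#' @param start Onset (ms).
#' @param duration Pulse length (ms).
#' @param amplitude Current (pA/pF).
#' @return A [StimulusSpec-class].
#' @export
edgeStimulus <- function(dims, rows = NULL, cols = NULL, start = 0,
                         duration = 2, amplitude = 52) {
  mask <- matrix(FALSE, dims[1], dims[2])
  if (is.null(rows) && is.null(cols)) stop("give rows and/or cols")
  mask[rows %||% seq_len(dims[1]), cols %||% seq_len(dims[2])] <- TRUE
  stimulusSpec(mask, start = start, duration = duration,
               amplitude = amplitude)
}
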