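# S4 containers for tissue geometry, simulation configuration and results.

#' FibrosisMap: spatial fibrosis-percentage field
#'
#' A scalar field f(x) in percent on the computational grid.  Drives both
#' the per-node obstacle probability and (optionally) the ionic
#' remodeling of surviving myocytes.
#'
#' @slot pct Numeric matrix of fibrosis percentages in \[0, 100\];
#'   rows/columns are grid nodes.
#' @slot spacing Node spacing dx in cm (0.025 cm = 250 um by default).
#' @exportClass FibrosisMap
setClass("FibrosisMap",
         representation(pct = "matrix", spacing = "numeric"))

setValidity("FibrosisMap", function(object) {
  if (!is.numeric(object@pct)) return("pct must be numeric")
  if (any(!is.finite(object@pct))) return("pct contains non-finite values")
  if (any(object@pct < 0 | object@pct > 100))
    return("fibrosis percentages must be within [0, 100]")
  if (length(object@spacing) != 1L || object@spacing <= 0)
    return("spacing must be a positive scalar (cm)")
  TRUE
})

#' ObstacleTexture: one seeded realization of a fibrosis map
#'
#' Boolean mask of electrically uncoupled, unexcitable nodes obtained by
#' thresholding a per-node uniform field against the local obstacle
#' probability f/100.
#'
#' @slot mask Logical matrix; `TRUE` marks an obstacle node.
#' @slot seed Integer seed the texture was drawn with.
#' @slot mapHash Content hash of the parent [FibrosisMap-class].
#' @exportClass ObstacleTexture
setClass("ObstacleTexture",
         representation(mask = "matrix", seed = "integer",
                        mapHash = "character"))

setValidity("ObstacleTexture", function(object) {
  if (!is.logical(object@mask)) return("mask must be logical")
  if (anyNA(object@mask)) return("mask contains NA")
  TRUE
})

#' ScarSpec: synthetic circular scar description
#'
#' @slot center Grid coordinates (row, col) of the scar center (may be
#'   fractional).
#' @slot diameter Scar diameter in cm.
#' @slot profile Either `"radial_linear"` (fibrosis falls linearly from
#'   `level` percent at the center to 0 at the rim) or `"uniform"`
#'   (constant `level` inside the disk).
#' @slot level Center fibrosis percentage (radial profile) or the uniform
#'   level.
#' @exportClass ScarSpec
setClass("ScarSpec",
         representation(center = "numeric", diameter = "numeric",
                        profile = "character", level = "numeric"))

setValidity("ScarSpec", function(object) {
  if (length(object@center) != 2L) return("center must be (row, col)")
  if (object@diameter <= 0) return("diameter must be positive (cm)")
  if (!object@profile %in% c("radial_linear", "uniform"))
    return("profile must be 'radial_linear' or 'uniform'")
  if (object@level < 0 || object@level > 100)
    return("level must be within [0, 100]")
  TRUE
})

#' ScarSpec constructor
#' @param center Grid coordinates (row, col) of the scar center.
#' @param diameter Scar diameter in cm.
#' @param profile `"radial_linear"` or `"uniform"`.
#' @param level Center (radial) or uniform fibrosis percentage.
#' @return A [ScarSpec-class] object.
#' @export
scarSpec <- function(center, diameter, profile = c("radial_linear", "uniform"),
                     level = 50) {
  new("ScarSpec", center = as.numeric(center), diameter = diameter,
      profile = match.arg(profile), level = level)
}

#' TissueGrid: geometry, obstacles and fibrosis of one tissue sheet
#'
#' @slot fibrosis The [FibrosisMap-class] of the sheet.
#' @slot obstacles The realized [ObstacleTexture-class]; obstacle nodes
#'   carry no state and exchange no current.
#' @exportClass TissueGrid
setClass("TissueGrid",
         representation(fibrosis = "FibrosisMap",
                        obstacles = "ObstacleTexture"))

setValidity("TissueGrid", function(object) {
  if (!identical(dim(object@fibrosis@pct), dim(object@obstacles@mask)))
    return("fibrosis map and obstacle mask dimensions differ")
  TRUE
})

#' TissueGrid constructor
#'
#' @param fibrosis A [FibrosisMap-class] (or plain percentage matrix).
#' @param obstacles An [ObstacleTexture-class]; when omitted, a texture is
#'   sampled from the map with `seed`.
#' @param seed Integer texture seed used when `obstacles` is missing.
#' @param spacing Node spacing in cm when `fibrosis` is a plain matrix.
#' @return A [TissueGrid-class].
#' @export
tissueGrid <- function(fibrosis, obstacles = NULL, seed = 1L,
                       spacing = 0.025) {
  if (is.matrix(fibrosis))
    fibrosis <- new("FibrosisMap", pct = fibrosis, spacing = spacing)
  if (is.null(obstacles))
    obstacles <- sampleTexture(fibrosis, seed = seed)
  new("TissueGrid", fibrosis = fibrosis, obstacles = obstacles)
}

#' StimulusSpec: one external stimulus
#'
#' @slot mask Logical matrix of stimulated nodes.
#' @slot start Onset time (ms).
#' @slot duration Pulse duration (ms), > 0.
#' @slot amplitude Current per capacitance (pA/pF), positive =
#'   depolarizing.
#' @exportClass StimulusSpec
setClass("StimulusSpec",
         representation(mask = "matrix", start = "numeric",
                        duration = "numeric", amplitude = "numeric"))

setValidity("StimulusSpec", function(object) {
  if (!is.logical(object@mask)) return("mask must be logical")
  if (!any(object@mask)) return("stimulus mask is empty")
  if (object@duration <= 0) return("duration must be positive")
  TRUE
})

#' StimulusSpec constructor
#' @param mask Logical matrix of stimulated nodes.
#' @param start Onset time (ms).
#' @param duration Pulse duration (ms).
#' @param amplitude Depolarizing current per capacitance (pA/pF).
#' @return A [StimulusSpec-class].
#' @export
stimulusSpec <- function(mask, start, duration = 2, amplitude = 52) {
  new("StimulusSpec", mask = mask, start = start, duration = duration,
      amplitude = amplitude)
}

#' SimConfig: numerical and recording configuration of one run
#'
#' @slot dt Integration time step in ms (0.02 by default).
#' @slot duration Simulated time in ms.
#' @slot gGap Gap-junction conductance in nS (103.6 by default).
#' @slot cmNode Node membrane capacitance in pF; together with `gGap` and
#'   the spacing it sets the coupling strength (and thereby the planar
#'   conduction velocity, calibrated to 72 cm/s at 1 Hz pacing).
#' @slot params Named TP06 parameter vector.
#' @slot remodeling Logical; apply fibrosis-dependent conductance scaling
#'   to surviving myocytes.
#' @slot frameStride Full-frame snapshot interval (ms; 0 disables).
#' @slot probeStride Probe sampling interval (ms).
#' @slot probes Two-column matrix (row, col) of probe nodes.
#' @slot ecgElectrode Electrode position (x, y, z) in cm for online
#'   pseudo-ECG recording; length 0 disables.
#' @slot seed Integer seed recorded with the run.
#' @slot eStride Steps between reversal-potential refreshes.
#' @exportClass SimConfig
setClass("SimConfig",
         representation(dt = "numeric", duration = "numeric",
                        gGap = "numeric", cmNode = "numeric",
                        params = "numeric", remodeling = "logical",
                        frameStride = "numeric", probeStride = "numeric",
                        probes = "matrix", ecgElectrode = "numeric",
                        seed = "integer", eStride = "integer"))

setValidity("SimConfig", function(object) {
  if (object@dt <= 0) return("dt must be positive")
  if (object@duration < 0) return("duration must be non-negative")
  if (object@gGap < 0) return("gGap must be non-negative")
  if (object@cmNode <= 0) return("cmNode must be positive")
  if (object@probeStride > 1) return("probe sampling interval must be <= 1 ms")
  TRUE
})

#' SimConfig constructor
#' @param duration Simulated time (ms).
#' @param dt Time step (ms).
#' @param gGap Gap-junction conductance (nS).
#' @param cmNode Node capacitance (pF); `NULL` takes the calibrated
#'   value carried by the parameter vector (every variant is calibrated
#'   so a planar wave travels at 72 cm/s at CL 1000 ms).
#' @param params TP06 parameter vector ([tp06Params()]).
#' @param remodeling Apply ionic remodeling from the fibrosis map.
#' @param frameStride Snapshot interval (ms), 0 = no frames.
#' @param probeStride Probe sampling interval (ms).
#' @param probes Two-column (row, col) matrix of probe nodes.
#' @param ecgElectrode Optional (x, y, z) electrode position (cm).
#' @param seed Integer seed stamped into recordings.
#' @param eStride Steps between reversal-potential refreshes
#'   (0.5 ms by default; the refresh is insensitive up to at least 1 ms).
#' @return A [SimConfig-class].
#' @export
simConfig <- function(duration, dt = 0.02, gGap = 103.6,
                      cmNode = NULL,
                      params = tp06Params(), remodeling = FALSE,
                      frameStride = 10, probeStride = 1,
                      probes = matrix(numeric(0), 0, 2),
                      ecgElectrode = numeric(0), seed = 1L,
                      eStride = 25L) {
  cmNode <- cmNode %||% attr(params, "cmNode") %||% ra_default_cm_node
  new("SimConfig", dt = dt, duration = duration, gGap = gGap,
      cmNode = cmNode, params = params, remodeling = remodeling,
      frameStride = frameStride, probeStride = probeStride,
      probes = probes, ecgElectrode = as.numeric(ecgElectrode),
      seed = as.integer(seed), eStride = as.integer(eStride))
}

#' SimRecording: stored output of one tissue run
#'
#' @slot frames Voltage snapshots, one column per frame (nodes in
#'   column-major grid order); obstacle nodes hold `NA`.
#' @slot frameTimes Times (ms) of the snapshots, monotonically increasing.
#' @slot probes Full-rate probe voltage traces, one column per probe.
#' @slot probeTimes Probe sample times (ms).
#' @slot probeIndex Two-column (row, col) matrix of probe locations.
#' @slot ecg Online pseudo-ECG samples (empty when not recorded).
#' @slot ecgTimes Times of the ECG samples (ms).
#' @slot actTime Matrix of first activation times (V upcrossing -20 mV)
#'   since the start of the run; `NA` where never activated.
#' @slot finalState Full per-node state matrix at the end of the run.
#' @slot grid The [TissueGrid-class] simulated.
#' @slot config The [SimConfig-class] used.
#' @slot configHash Content hash of (grid, config, stimuli).
#' @slot stopReason `"completed"`, `"all_quiet"` or `"target_activated"`.
#' @slot stopTime Early-exit time (ms) or `NA`.
#' @exportClass SimRecording
setClass("SimRecording",
         representation(frames = "matrix", frameTimes = "numeric",
                        probes = "matrix", probeTimes = "numeric",
                        probeIndex = "matrix",
                        ecg = "numeric", ecgTimes = "numeric",
                        actTime = "matrix", finalState = "matrix",
                        grid = "TissueGrid", config = "SimConfig",
                        configHash = "character", stopReason = "character",
                        stopTime = "numeric"))

setValidity("SimRecording", function(object) {
  if (length(object@frameTimes) > 1 && any(diff(object@frameTimes) <= 0))
    return("frame times must be strictly increasing")
  if (length(object@ecg) != length(object@ecgTimes))
    return("ecg and ecgTimes lengths differ")
  TRUE
})

#' OutcomeRecord: classification of one simulation run
#'
#' @slot label One of `"terminated"`, `"anchored_single_cw"`,
#'   `"anchored_single_ccw"`, `"anchored_multi"`, `"not_anchored"`.
#' @slot period Measured excitation period (ms); censored values equal
#'   the measurement window length.
#' @slot classificationTime Time (ms) the classifier was applied at.
#' @slot timeToAnchor Earliest time (ms) from which the anchored (or
#'   terminated) criterion holds through the end of the run; `NA` for
#'   `not_anchored`.
#' @slot nArms Number of arms of an anchored rotor (same-sign phase
#'   singularities in the scar annulus); 0 when not applicable.
#' @slot seed Seed of the underlying run.
#' @slot configHash Hash of the underlying run configuration.
#' @exportClass OutcomeRecord
setClass("OutcomeRecord",
         representation(label = "character", period = "numeric",
                        classificationTime = "numeric",
                        timeToAnchor = "numeric", nArms = "integer",
                        seed = "integer", configHash = "character"))

setValidity("OutcomeRecord", function(object) {
  ok <- c("terminated", "anchored_single_cw", "anchored_single_ccw",
          "anchored_multi", "not_anchored", "failed")
  if (!object@label %in% ok)
    return(paste("label must be one of:", paste(ok, collapse = ", ")))
  TRUE
})

#' ECGConfig: pseudo-ECG computation settings
#'
#' @slot electrode Electrode position (x, y, z) in cm; the tissue sheet
#'   lies in the z = 0 plane with x along grid rows and y along columns.
#' @slot diffusion Scalar effective diffusion coefficient D (cm^2/ms)
#'   entering the dipole integrand; `NA` means "derive from the run
#'   configuration" as g_gap dx^2 / C_m.
#' @exportClass ECGConfig
setClass("ECGConfig",
         representation(electrode = "numeric", diffusion = "numeric"))

setValidity("ECGConfig", function(object) {
  if (length(object@electrode) != 3L) return("electrode must be (x, y, z)")
  TRUE
})

#' ECGConfig constructor
#' @param electrode Electrode (x, y, z) position in cm.
#' @param diffusion Effective diffusion (cm^2/ms); `NA` = derive from run.
#' @return An [ECGConfig-class].
#' @export
ecgConfig <- function(electrode, diffusion = NA_real_) {
  new("ECGConfig", electrode = as.numeric(electrode),
      diffusion = diffusion)
}

#' S1S2Spec: cross-field rotor initiation parameters
#'
#' @slot tip Intended rotor-tip grid position (row, col).
#' @slot s1Rows Rows stimulated by the S1 planar stimulus.
#' @slot s1Times Onset times (ms) of the S1 beats.  A short two-beat
#'   train (0, 340 ms) preconditions the tissue through restitution so
#'   the nascent spiral's wavelength fits compact sheets.
#' @slot s2Cols Columns covered by the S2 half-plane.
#' @slot wavebackLevel Voltage level (mV) whose falling crossing at the
#'   tip position triggers S2.
#' @exportClass S1S2Spec
setClass("S1S2Spec",
         representation(tip = "numeric", s1Rows = "integer",
                        s1Times = "numeric", s2Cols = "integer",
                        wavebackLevel = "numeric"))

#' S1S2Spec constructor
#' @param tip Intended tip (row, col).
#' @param s1Rows Rows carrying the S1 stimulus (default 1:3).
#' @param s1Times S1 beat times (ms), default `c(0, 340)`.
#' @param s2Cols Columns of the S2 half-plane (default: everything left
#'   of the tip column).
#' @param wavebackLevel S2 trigger level (mV).
#' @return An [S1S2Spec-class].
#' @export
s1s2Spec <- function(tip, s1Rows = 1:3, s1Times = c(0, 340),
                     s2Cols = NULL, wavebackLevel = -60) {
  if (is.null(s2Cols)) s2Cols <- seq_len(max(1L, floor(tip[2])))
  new("S1S2Spec", tip = as.numeric(tip), s1Rows = as.integer(s1Rows),
      s1Times = as.numeric(s1Times), s2Cols = as.integer(s2Cols),
      wavebackLevel = wavebackLevel)
}
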