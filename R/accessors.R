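# Accessor generics and show methods.

#' @describeIn FibrosisMap-class fibrosis percentages as a matrix
#' @param object,x An object.
#' @export
setGeneric("fibrosisPct", function(object) standardGeneric("fibrosisPct"))
#' @export
setMethod("fibrosisPct", "FibrosisMap", function(object) object@pct)
#' @export
setMethod("fibrosisPct", "TissueGrid", function(object) object@fibrosis@pct)

#' Obstacle mask accessor
#' @param object An [ObstacleTexture-class] or [TissueGrid-class].
#' @export
setGeneric("obstacleMask", function(object) standardGeneric("obstacleMask"))
#' @export
setMethod("obstacleMask", "ObstacleTexture", function(object) object@mask)
#' @export
setMethod("obstacleMask", "TissueGrid", function(object) object@obstacles@mask)

#' Node spacing (cm) accessor
#' @param object A grid-bearing object.
#' @export
setGeneric("spacing", function(object) standardGeneric("spacing"))
#' @export
setMethod("spacing", "FibrosisMap", function(object) object@spacing)
#' @export
setMethod("spacing", "TissueGrid", function(object) object@fibrosis@spacing)
#' @export
setMethod("spacing", "SimRecording", function(object) spacing(object@grid))

#' Grid dimensions (rows, cols)
#' @param object A grid-bearing object.
#' @export
setGeneric("gridDim", function(object) standardGeneric("gridDim"))
#' @export
setMethod("gridDim", "FibrosisMap", function(object) dim(object@pct))
#' @export
setMethod("gridDim", "TissueGrid", function(object) dim(object@fibrosis@pct))
#' @export
setMethod("gridDim", "SimRecording", function(object) gridDim(object@grid))

#' Voltage frames of a recording
#' @param object A [SimRecording-class].
#' @export
setGeneric("voltageFrames", function(object) standardGeneric("voltageFrames"))
#' @export
setMethod("voltageFrames", "SimRecording", function(object) object@frames)

#' Frame times (ms) of a recording
#' @param object A [SimRecording-class].
#' @export
setGeneric("frameTimes", function(object) standardGeneric("frameTimes"))
#' @export
setMethod("frameTimes", "SimRecording", function(object) object@frameTimes)

#' Probe voltage traces
#' @param object A [SimRecording-class].
#' @export
setGeneric("probeTraces", function(object) standardGeneric("probeTraces"))
#' @export
setMethod("probeTraces", "SimRecording", function(object) object@probes)

#' Probe sample times (ms)
#' @param object A [SimRecording-class].
#' @export
setGeneric("probeTimes", function(object) standardGeneric("probeTimes"))
#' @export
setMethod("probeTimes", "SimRecording", function(object) object@probeTimes)

#' Final full tissue state of a recording
#' @param object A [SimRecording-class].
#' @export
setGeneric("finalState", function(object) standardGeneric("finalState"))
#' @export
setMethod("finalState", "SimRecording", function(object) object@finalState)

#' One voltage frame as a grid matrix
#'
#' @param object A [SimRecording-class].
#' @param t Requested time (ms); the nearest stored frame is returned.
#' @return Numeric matrix (rows x cols) of voltages; obstacle nodes `NA`.
#' @export
setGeneric("voltageFrame", function(object, t) standardGeneric("voltageFrame"))
#' @export
setMethod("voltageFrame", "SimRecording", function(object, t) {
  if (!length(object@frameTimes)) stop("recording holds no frames")
  k <- which.min(abs(object@frameTimes - t))
  d <- gridDim(object)
  m <- matrix(object@frames[, k], d[1], d[2])
  m[obstacleMask(object@grid)] <- NA_real_
  m
})

#' Outcome label accessor
#' @param object An [OutcomeRecord-class].
#' @export
setGeneric("outcomeLabel", function(object) standardGeneric("outcomeLabel"))
#' @export
setMethod("outcomeLabel", "OutcomeRecord", function(object) object@label)

#' @export
setMethod("show", "FibrosisMap", function(object) {
  d <- dim(object@pct)
  cat(sprintf("FibrosisMap: %d x %d nodes (dx = %g cm), f in [%.1f, %.1f]%%\n",
              d[1], d[2], object@spacing, min(object@pct), max(object@pct)))
})

#' @export
setMethod("show", "ObstacleTexture", function(object) {
  cat(sprintf("ObstacleTexture: %d x %d, %d obstacles (%.1f%%), seed %d\n",
              nrow(object@mask), ncol(object@mask), sum(object@mask),
              100 * mean(object@mask), object@seed))
})

#' @export
setMethod("show", "TissueGrid", function(object) {
  d <- gridDim(object)
  cat(sprintf("TissueGrid: %d x %d nodes (%.2f x %.2f cm), %d obstacle nodes\n",
              d[1], d[2], d[1] * spacing(object), d[2] * spacing(object),
              sum(obstacleMask(object))))
})

#' @export
setMethod("show", "SimConfig", function(object) {
  cat(sprintf(paste0("SimConfig: duration %g ms, dt %g ms, g_gap %g nS, ",
                     "Cm %g pF, remodeling %s\n"),
              object@duration, object@dt, object@gGap, object@cmNode,
              object@remodeling))
})

#' @export
setMethod("show", "SimRecording", function(object) {
  cat(sprintf(paste0("SimRecording: %d frames (stride %g ms), %d probes, ",
                     "%s, hash %s\n"),
              ncol(object@frames), object@config@frameStride,
              ncol(object@probes), object@stopReason, object@configHash))
})

#' @export
setMethod("show", "OutcomeRecord", function(object) {
  cat(sprintf("OutcomeRecord: %s (period %.1f ms at t = %g ms%s)\n",
              object@label, object@period, object@classificationTime,
              if (is.finite(object@timeToAnchor))
                sprintf(", settled at %.2f s", object@timeToAnchor / 1000)
              else ""))
})

#' Convert an OutcomeRecord to a one-row data.frame
#' @param x An [OutcomeRecord-class].
#' @param ... Unused.
#' @export
as.data.frame.OutcomeRecord <- function(x, ...) {
  data.frame(label = x@label, period = x@period,
             classification_time = x@classificationTime,
             time_to_anchor = x@timeToAnchor, n_arms = x@nArms,
             seed = x@seed, config_hash = x@configHash,
             stringsAsFactors = FALSE)
}
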