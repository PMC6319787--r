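# Phase-singularity detection and tracking, period measurement, and
# outcome classification of re-entrant activation patterns.

#' Detect phase singularities in a pair of voltage frames
#'
#' Builds the time-delay embedding phase
#' \eqn{\theta = \mathrm{atan2}(V(t) - V^*, V(t-\tau) - V^*)} and reports
#' every grid plaquette around which the winding number of \eqn{\theta}
#' is \eqn{\pm 2\pi}.  The sign of the winding is the topological charge;
#' positive charge corresponds to counter-clockwise rotation in grid
#' coordinates with the row index increasing downward.  Plaquettes
#' containing an obstacle corner are skipped (phase is undefined there).
#'
#' @param v1 Voltage frame at time t (matrix, or vector in grid order).
#' @param v0 Voltage frame at time t - tau.
#' @param obstacle Logical obstacle mask (default: none).
#' @param vstar Phase origin V* in mV.
#' @return data.frame with `row`, `col` (plaquette centers, fractional)
#'   and `charge` (+1 or -1).
#' @export
detectPhaseSingularities <- function(v1, v0, obstacle = NULL, vstar = -40) {
  if (is.matrix(v1)) { nr <- nrow(v1); nc <- ncol(v1) }
  else stop("v1 must be a matrix")
  if (!identical(dim(v0), dim(v1))) stop("frame dimensions differ")
  if (is.null(obstacle)) obstacle <- matrix(FALSE, nr, nc)
  v1[is.na(v1)] <- vstar; v0[is.na(v0)] <- vstar
  .detect_ps_cpp(as.vector(v1), as.vector(v0), nr, nc,
                 as.vector(obstacle), vstar)
}

#' Detect phase singularities in a recording at a given time
#'
#' @param recording A [SimRecording-class] with frames.
#' @param t Analysis time (ms); the nearest stored frame is used.
#' @param tau Embedding delay (ms); must be a multiple of the frame
#'   stride.
#' @param vstar Phase origin (mV).
#' @return data.frame of singularities (`row`, `col`, `charge`, `time`).
#' @export
detectSingularities <- function(recording, t, tau = 20, vstar = -40) {
  ft <- frameTimes(recording)
  if (length(ft) < 2) stop("recording holds too few frames")
  k1 <- which.min(abs(ft - t))
  k0 <- which.min(abs(ft - (ft[k1] - tau)))
  if (k0 == k1) k0 <- k1 - 1
  d <- gridDim(recording)
  ps <- detectPhaseSingularities(
    matrix(voltageFrames(recording)[, k1], d[1], d[2]),
    matrix(voltageFrames(recording)[, k0], d[1], d[2]),
    obstacleMask(recording@grid), vstar)
  if (nrow(ps)) ps$time <- ft[k1] else ps$time <- numeric(0)
  ps
}

#' Track phase singularities over all frames
#'
#' @param recording A [SimRecording-class].
#' @param tau Embedding delay (ms).
#' @param vstar Phase origin (mV).
#' @return data.frame of singularities over time (`time`, `row`, `col`,
#'   `charge`).
#' @export
trackSingularities <- function(recording, tau = 20, vstar = -40) {
  ft <- frameTimes(recording)
  stride <- if (length(ft) > 1) ft[2] - ft[1] else Inf
  lag <- max(1L, round(tau / stride))
  out <- vector("list", length(ft))
  d <- gridDim(recording)
  for (k in seq_along(ft)) {
    if (k <= lag) next
    ps <- detectPhaseSingularities(
      matrix(voltageFrames(recording)[, k], d[1], d[2]),
      matrix(voltageFrames(recording)[, k - lag], d[1], d[2]),
      obstacleMask(recording@grid), vstar)
    if (nrow(ps)) out[[k]] <- cbind(time = ft[k], ps)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(time = numeric(0), row = numeric(0),
                      col = numeric(0), charge = numeric(0))
  res
}

# upward crossing times of `level` in a sampled trace
upcrossings <- function(times, v, level = -20) {
  i <- which(v[-1] >= level & v[-length(v)] < level)
  times[i + 1]
}

#' Period of the excitation pattern
#'
#' The period is the median inter-activation interval (upward crossings
#' of -20 mV) pooled over all probe traces within the measurement window
#' ending at `windowEnd`.  A probe with no activation in the window
#' contributes the window length itself (its local period is censored at
#' the window), a probe with a single activation contributes nothing,
#' so a quiescent or very slow pattern reports a right-censored period
#' equal to `window`.
#'
#' @param recording A [SimRecording-class] with probe traces.
#' @param windowEnd End of the measurement window (ms); default = end of
#'   the recording.
#' @param window Window length (ms), 320 by default.
#' @return Period in ms.
#' @export
measurePeriod <- function(recording, windowEnd = NULL, window = 320) {
  tr <- probeTraces(recording); tt <- probeTimes(recording)
  if (!ncol(tr)) stop("recording has no probe traces")
  windowEnd <- windowEnd %||% max(tt)
  sel <- tt > windowEnd - window & tt <= windowEnd
  if (!any(sel)) stop("measurement window lies outside the recording")
  intervals <- unlist(lapply(seq_len(ncol(tr)), function(q) {
    a <- upcrossings(tt[sel], tr[sel, q])
    if (length(a) == 0) window
    else if (length(a) == 1) numeric(0)
    else diff(a)
  }))
  if (!length(intervals)) return(window)
  median(intervals)
}

#' Classify the outcome of a run
#'
#' Applies the outcome rules at `classificationTime`: the pattern is
#' `terminated` when every myocyte is below -20 mV; otherwise it is
#' anchored when the excitation period exceeds 280 ms over a 320 ms
#' measuring window (anchored rotation around the scar is slow anatomical
#' re-entry, while a free rotor turns close to 222 ms); anchored patterns
#' are subdivided by the number of same-sign phase singularities within
#' a 1 cm annulus around the scar rim (single clockwise, single
#' counter-clockwise, or multi-armed).  Everything else is
#' `not_anchored`.
#'
#' @param recording A [SimRecording-class] with probes and frames.
#' @param scar The [ScarSpec-class] of the run (or `NULL` for scar-free
#'   controls, in which case arm counting uses the whole domain).
#' @param classificationTime Time (ms) to classify at; default = end of
#'   the recording.  The recording must extend to this time.
#' @param periodThreshold Anchoring period bound (ms).
#' @param window Period measurement window (ms).
#' @return An [OutcomeRecord-class].
#' @export
classifyOutcome <- function(recording, scar = NULL,
                            classificationTime = NULL,
                            periodThreshold = 280, window = 320) {
  ft <- frameTimes(recording)
  tc <- classificationTime %||% max(ft)
  if (max(ft) + 1e-6 < tc)
    stop(sprintf("recording ends at %g ms; %g ms required", max(ft), tc))
  vEnd <- voltageFrames(recording)[, which.min(abs(ft - tc))]
  mk <- function(label, period, tta, arms) {
    new("OutcomeRecord", label = label, period = period,
        classificationTime = tc, timeToAnchor = tta,
        nArms = as.integer(arms), seed = recording@config@seed,
        configHash = recording@configHash)
  }
  if (all(vEnd < -20, na.rm = TRUE))
    return(mk("terminated", measurePeriod(recording, tc, window),
              timeToAnchor(recording, scar), 0L))
  period <- measurePeriod(recording, tc, window)
  if (period > periodThreshold) {
    ps <- detectSingularities(recording, tc)
    if (!is.null(scar) && nrow(ps)) {
      dx <- spacing(recording)
      dist <- sqrt((ps$row - scar@center[1])^2 +
                   (ps$col - scar@center[2])^2) * dx
      ps <- ps[abs(dist - scar@diameter / 2) <= 1, , drop = FALSE]
    }
    arms <- if (nrow(ps)) max(sum(ps$charge > 0), sum(ps$charge < 0)) else 1L
    chir <- if (nrow(ps) && sum(ps$charge) < 0) "cw" else "ccw"
    label <- if (arms >= 2) "anchored_multi"
             else paste0("anchored_single_", chir)
    return(mk(label, period, timeToAnchor(recording, scar), arms))
  }
  mk("not_anchored", period, NA_real_, 0L)
}

#' Time until the pattern settled (anchored or terminated)
#'
#' For an eventually-anchored run: the earliest time from which the
#' period criterion (> 280 ms over a sliding 320 ms window) holds
#' continuously until the end of the recording; a transient excursion
#' above the threshold that later reverts is ignored.  For a terminated
#' run: the time of the last suprathreshold (>= -20 mV) sample.
#'
#' @param recording A [SimRecording-class].
#' @param scar Unused placeholder for symmetry with [classifyOutcome()].
#' @param periodThreshold,window As in [classifyOutcome()].
#' @param stride Spacing (ms) of tested window ends.
#' @return Time in ms (`NA` if the criterion never holds).
#' @export
timeToAnchor <- function(recording, scar = NULL, periodThreshold = 280,
                         window = 320, stride = 10) {
  ft <- frameTimes(recording)
  vF <- voltageFrames(recording)
  quiet <- apply(vF < -20, 2, all)
  quiet[is.na(quiet)] <- FALSE
  if (length(quiet) && quiet[length(quiet)]) {
    lastOn <- suppressWarnings(max(ft[!quiet]))
    return(if (is.finite(lastOn)) lastOn else ft[1])
  }
  tt <- probeTimes(recording)
  ends <- seq(min(tt) + window, max(tt), by = stride)
  if (!length(ends)) return(NA_real_)
  slow <- vapply(ends, function(e)
    measurePeriod(recording, e, window) > periodThreshold, TRUE)
  if (!slow[length(slow)]) return(NA_real_)
  run <- rev(cumprod(rev(slow)))  # 1 where slow holds through the end
  ends[which(run == 1)[1]] - window
}
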