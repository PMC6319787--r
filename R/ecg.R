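# Dipole-source pseudo-ECG:
#   ECG(t) = sum_i  (r_i . D grad V_i) / |r_i|^3  dA
# over myocyte nodes, with the gradient by central differences
# (one-sided at obstacles and boundaries).  Only relative units are
# meaningful; D is the scalar effective diffusion g_gap dx^2 / C_m
# implied by the discrete coupling.

gradFrame <- function(vm, obst, dx) {
  nr <- nrow(vm); nc <- ncol(vm)
  v <- vm; v[obst] <- NA_real_
  up <- rbind(NA_real_, v[-nr, ]); dn <- rbind(v[-1, ], NA_real_)
  lf <- cbind(NA_real_, v[, -nc]); rt <- cbind(v[, -1], NA_real_)
  central <- function(a, b) {
    g <- (b - a) / (2 * dx)
    one_b <- (b - v) / dx; one_a <- (v - a) / dx
    g[is.na(g)] <- one_b[is.na(g)]
    g[is.na(g)] <- one_a[is.na(g)]
    g[is.na(g)] <- 0
    g
  }
  list(gx = central(up, dn), gy = central(lf, rt))
}

#' Compute the pseudo-ECG of a recording
#'
#' Evaluates the dipole-density sum over all stored frames.  The
#' electrode must lie at least 1 cm away from the tissue sheet (which
#' occupies the z = 0 plane).
#'
#' @param recording A [SimRecording-class] with frames.
#' @param cfg An [ECGConfig-class]; when its `diffusion` is `NA` the
#'   effective diffusion of the run configuration is used.
#' @return List with `times` (ms) and `amplitudes` (arbitrary units).
#' @examples
#' \dontrun{
#' ecg <- computeECG(rec, ecgConfig(c(3.2, 3.2, 10)))
#' }
#' @export
computeECG <- function(recording, cfg) {
  stopifnot(is(cfg, "ECGConfig"))
  validObject(cfg)
  d <- gridDim(recording); dx <- spacing(recording)
  D <- cfg@diffusion
  if (is.na(D))
    D <- recording@config@gGap / recording@config@cmNode * dx^2
  obst <- obstacleMask(recording@grid)
  x <- (seq_len(d[1]) - 1) * dx; y <- (seq_len(d[2]) - 1) * dx
  rx <- outer(cfg@electrode[1] - x, rep(1, d[2]))
  ry <- outer(rep(1, d[1]), cfg@electrode[2] - y)
  rz <- cfg@electrode[3]
  rmag <- sqrt(rx^2 + ry^2 + rz^2)
  if (min(rmag) < 1)
    stop("electrode must be at least 1 cm from the tissue")
  wx <- D * rx / rmag^3 * dx^2; wy <- D * ry / rmag^3 * dx^2
  wx[obst] <- 0; wy[obst] <- 0
  ft <- frameTimes(recording)
  amps <- vapply(seq_along(ft), function(k) {
    vm <- matrix(voltageFrames(recording)[, k], d[1], d[2])
    vm[is.na(vm)] <- 0   # obstacle nodes carry no source
    g <- gradFrame(vm, obst, dx)
    sum(wx * g$gx + wy * g$gy, na.rm = TRUE)
  }, 0)
  list(times = ft, amplitudes = amps)
}

#' Per-beat features of a pseudo-ECG trace
#'
#' Detects beats as prominent local maxima and reports cycle lengths and
#' an amplitude-variability index: the coefficient of variation of peak
#' amplitudes in a sliding 5-beat window.  Monomorphic tachycardia gives
#' a low index, polymorphic a high one.
#'
#' @param times,amplitudes The ECG trace.
#' @param minSeparation Minimum beat spacing (ms).
#' @param prominence Fraction of the trace range a peak must rise above
#'   the detection floor.
#' @return List with `peakTimes`, `peakAmplitudes`, `cycleLengths` and
#'   `variability` (one CV per 5-beat window).
#' @export
beatFeatures <- function(times, amplitudes, minSeparation = 120,
                         prominence = 0.3) {
  if (length(times) != length(amplitudes)) stop("length mismatch")
  rng <- range(amplitudes)
  floorLevel <- rng[1] + prominence * diff(rng)
  above <- amplitudes > floorLevel
  if (!any(above)) stop("no beats detected")
  # contiguous excursions above the floor; one peak per excursion
  starts <- which(above & !c(FALSE, above[-length(above)]))
  ends <- which(above & !c(above[-1], FALSE))
  pk <- vapply(seq_along(starts), function(k) {
    i <- starts[k]:ends[k]; i[which.max(amplitudes[i])]
  }, 0L)
  # enforce separation
  if (length(pk) > 1) {
    keep <- pk[1]
    for (i in pk[-1])
      if (times[i] - times[keep[length(keep)]] >= minSeparation)
        keep <- c(keep, i)
      else if (amplitudes[i] > amplitudes[keep[length(keep)]])
        keep[length(keep)] <- i
    pk <- keep
  }
  if (length(pk) < 3)
    stop("fewer than 3 beats detected; features undefined")
  amps <- amplitudes[pk]
  vari <- if (length(pk) >= 5)
    vapply(seq_len(length(pk) - 4), function(k) {
      w <- amps[k:(k + 4)]; sd(w) / mean(w)
    }, 0)
  else sd(amps) / mean(amps)
  list(peakTimes = times[pk], peakAmplitudes = amps,
       cycleLengths = diff(times[pk]), variability = vari)
}
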