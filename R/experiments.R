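# Experiment drivers: distance sweeps, anchoring-time curves and the
# scar-size x fibrosis-level phase diagram.  Each driver runs independent
# seeded simulations, classifies every run and returns a tidy table; a
# failed run is recorded as "failed", never dropped.  Desk-scale defaults
# (see the methods vignette) keep one sweep within workstation reach;
# `fullScale = TRUE` restores the full domain and duration.

defaultSweepDims <- function(fullScale) {
  if (fullScale) c(512, 1024) else c(256, 512)
}

# shared worker: one scar run with a rotor initiated at a given distance
# from the scar rim; returns an OutcomeRecord (or "failed")
anchoringRun <- function(distanceCm, diameter, profile, level, seed,
                         remodeling, dims, duration, classificationTime,
                         params, cmNode = NULL) {
  dx <- 0.025
  out <- tryCatch({
    sg <- makeScarGrid(dims, diameter = diameter, profile = profile,
                       level = level, seed = seed)
    rimCol <- sg$spec@center[2] - diameter / 2 / dx
    tip <- c(dims[1] / 2, rimCol - distanceCm / dx)
    if (tip[2] < 20)
      stop("distance places the rotor outside the domain")
    cfg <- simConfig(duration = duration, params = params, seed = seed,
                     remodeling = remodeling, cmNode = cmNode,
                     probes = rbind(probeRing(sg$spec@center,
                                              diameter / 2 + 1, 16,
                                              sg$grid),
                                    probeRing(tip, 1.2, 4, sg$grid)))
    ini <- initiateRotor(sg$grid, cfg, s1s2Spec(tip))
    cont <- simConfig(duration = duration - ini$endTime, params = params,
                      seed = seed, remodeling = remodeling,
                      cmNode = cmNode, probes = cfg@probes)
    rec <- runTissue(sg$grid, cont, list(), init = ini$state,
                     t0 = ini$endTime)
    classifyOutcome(rec, sg$spec, classificationTime)
  }, error = function(e) {
    new("OutcomeRecord", label = "failed", period = NA_real_,
        classificationTime = classificationTime, timeToAnchor = NA_real_,
        nArms = 0L, seed = as.integer(seed), configHash = conditionMessage(e))
  })
  out
}

#' Outcome of rotor initiation versus distance from the scar
#'
#' For each (distance, texture seed) pair a rotor is initiated by S1S2 at
#' the given distance from the scar border and the final activation
#' pattern is classified.  Aggregated outcome fractions per distance are
#' attached as an attribute.
#'
#' @param distances Distances (cm) from the scar rim to the rotor tip.
#' @param seeds Texture seeds per distance.
#' @param diameter,profile,level Scar description (see [scarSpec()]).
#' @param remodeling Apply ionic remodeling.
#' @param dims Grid dimensions; default desk scale 256 x 512.
#' @param duration Simulated time per run (ms).
#' @param classificationTime Classifier time (ms); default = `duration`.
#' @param params TP06 parameter vector.
#' @param fullScale Use the full-scale domain (1024 x 512 nodes, 40 s).
#' @return data.frame with one row per run (distance, seed, label,
#'   period, time_to_anchor, ...); aggregation in
#'   `attr(, "fractions")`.
#' @export
runDistanceSweep <- function(distances, seeds = 1:10, diameter = 6.4,
                             profile = "radial_linear", level = 50,
                             remodeling = FALSE, dims = NULL,
                             duration = NULL, classificationTime = NULL,
                             params = tp06Params(), fullScale = FALSE) {
  dims <- dims %||% defaultSweepDims(fullScale)
  duration <- duration %||% (if (fullScale) 40000 else 20000)
  classificationTime <- classificationTime %||% duration
  runs <- expand.grid(distance = distances, seed = seeds)
  rows <- lapply(seq_len(nrow(runs)), function(k) {
    rec <- anchoringRun(runs$distance[k], diameter, profile, level,
                        runs$seed[k], remodeling, dims, duration,
                        classificationTime, params)
    cbind(distance = runs$distance[k], as.data.frame(rec))
  })
  tab <- do.call(rbind, rows)
  attr(tab, "fractions") <-
    as.data.frame.table(prop.table(table(distance = tab$distance,
                                         label = tab$label), 1),
                        responseName = "fraction")
  tab
}

#' Anchoring time versus initial distance
#'
#' Measures, per (distance, seed, remodeling arm), the time until the
#' pattern settled (anchored or terminated) and fits a linear model of
#' time on distance per arm.
#'
#' @inheritParams runDistanceSweep
#' @param remodelingArms Logical vector of remodeling settings to run.
#' @return data.frame of per-run times; the per-arm linear fits (slope,
#'   intercept, confidence intervals) are in `attr(, "fits")`.
#' @export
runAnchorTime <- function(distances, seeds = 1:10,
                          remodelingArms = c(FALSE, TRUE), diameter = 6.4,
                          profile = "radial_linear", level = 50,
                          dims = NULL, duration = NULL,
                          classificationTime = NULL,
                          params = tp06Params(), fullScale = FALSE) {
  dims <- dims %||% defaultSweepDims(fullScale)
  duration <- duration %||% (if (fullScale) 40000 else 20000)
  classificationTime <- classificationTime %||% duration
  runs <- expand.grid(distance = distances, seed = seeds,
                      remodeling = remodelingArms)
  rows <- lapply(seq_len(nrow(runs)), function(k) {
    rec <- anchoringRun(runs$distance[k], diameter, profile, level,
                        runs$seed[k], runs$remodeling[k], dims, duration,
                        classificationTime, params)
    cbind(distance = runs$distance[k], remodeling = runs$remodeling[k],
          as.data.frame(rec))
  })
  tab <- do.call(rbind, rows)
  ok <- !is.na(tab$time_to_anchor)
  fits <- lapply(split(tab[ok, ], tab$remodeling[ok]), function(d) {
    if (nrow(d) < 3) return(NULL)
    m <- lm(I(time_to_anchor / 1000) ~ distance, data = d)
    list(coef = coef(m), confint = confint(m))
  })
  attr(tab, "fits") <- fits
  tab
}

#' Anchoring phase diagram over scar size and fibrosis level
#'
#' Runs the uniform-fibrosis scar protocol with the rotor initiated at a
#' fixed distance for every (diameter, level) combination and labels each
#' cell `"Attraction"` when the anchored fraction exceeds 0.65.
#'
#' @param diameters Scar diameters (cm).
#' @param levels Uniform fibrosis percentages.
#' @param distance Rotor distance from the scar rim (cm), 5 by default.
#' @inheritParams runDistanceSweep
#' @return data.frame (diameter, level, fraction_anchored, label).
#' @export
runPhaseDiagram <- function(diameters, levels, distance = 5, seeds = 1:10,
                            remodeling = FALSE, dims = NULL,
                            duration = NULL, classificationTime = NULL,
                            params = tp06Params(), fullScale = FALSE) {
  dims <- dims %||% defaultSweepDims(fullScale)
  duration <- duration %||% (if (fullScale) 40000 else 20000)
  classificationTime <- classificationTime %||% duration
  cells <- expand.grid(diameter = diameters, level = levels)
  out <- lapply(seq_len(nrow(cells)), function(k) {
    labels <- vapply(seeds, function(s) {
      rec <- anchoringRun(distance, cells$diameter[k], "uniform",
                          cells$level[k], s, remodeling, dims, duration,
                          classificationTime, params)
      rec@label
    }, "")
    fa <- mean(grepl("^anchored", labels))
    data.frame(diameter = cells$diameter[k], level = cells$level[k],
               fraction_anchored = fa,
               label = if (fa > 0.65) "Attraction" else "No Attraction")
  })
  do.call(rbind, out)
}

#' Scar-free and necrotic-only control runs
#'
#' Initiates a rotor in the two control geometries and verifies the
#' free-rotor behavior: the rotor stays near its initial position and
#' the pattern is never classified as anchored.
#'
#' @param dims Grid dimensions.
#' @param duration Simulated time (ms) after initiation.
#' @param diameter Diameter (cm) of the necrotic control disk.
#' @param tip Rotor tip (row, col); default = domain quarter point.
#' @param params TP06 parameter vector.
#' @param cmNode Node capacitance (pF).
#' @return List of two elements (`no_scar`, `necrotic_only`), each with
#'   the [OutcomeRecord-class], the tip track, and the final tip
#'   displacement (cm) from the initiation point.
#' @export
runControls <- function(dims = c(256, 384), duration = 5000,
                        diameter = 3.2, tip = NULL,
                        params = tp06Params(), cmNode = NULL) {
  dx <- 0.025
  radiusNodes <- diameter / 2 / dx
  scarCenter <- c(dims[1] / 2, dims[2] - radiusNodes - 12)
  spec <- scarSpec(scarCenter, diameter, "uniform", 50)
  ctl <- makeControls(spec, dims)
  tip <- tip %||% c(dims[1] / 2, dims[2] / 4)
  lapply(ctl, function(grid) {
    cfg <- simConfig(duration = duration, params = params, cmNode = cmNode,
                     probes = rbind(probeRing(scarCenter, diameter / 2 + 1,
                                              16, grid),
                                    probeRing(tip, 1.2, 4, grid)))
    ini <- initiateRotor(grid, cfg, s1s2Spec(tip))
    cont <- simConfig(duration = duration, params = params,
                      cmNode = cmNode, probes = cfg@probes)
    rec <- runTissue(grid, cont, list(), init = ini$state,
                     t0 = ini$endTime)
    track <- trackSingularities(rec)
    lastT <- max(track$time)
    fin <- track[track$time == lastT, , drop = FALSE]
    disp <- min(sqrt((fin$row - ini$tip$row)^2 +
                     (fin$col - ini$tip$col)^2)) * dx
    list(outcome = classifyOutcome(rec, spec), track = track,
         displacementCm = disp, initialTip = ini$tip)
  })
}
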