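# Heavy simulations shared across test files (computed once per session).

.runCache <- new.env(parent = emptyenv())

sharedRun <- function(name, make) {
  if (is.null(.runCache[[name]])) .runCache[[name]] <- make()
  .runCache[[name]]
}

# Free rotor in a homogeneous 240 x 240 sheet: the rotation-period check,
# the scar-free control, and the parent state for the scar-imposition
# continuations below.
sharedFreeRotor <- function()
  sharedRun("freeRotor", function()
    freeRotorPeriod(dims = c(240, 240), duration = 1400,
                    measureWindow = 800, params = tp06Params("spiral")))

# mean tip position over a time slice of a singularity track
meanTip <- function(track, from, to) {
  sel <- track$time >= from & track$time <= to
  c(mean(track$row[sel]), mean(track$col[sel]))
}

# Embed the free-rotor final state into a (possibly padded) canvas whose
# grid carries an imposed scar, and continue the run.  This produces the
# post-anchoring configuration directly: the re-entrant wave keeps
# rotating and reorganizes around the scar.
continueWithScar <- function(fr, grid, duration, probes, pad = 0L) {
  nOld <- 240L; nNew <- nOld + 2L * pad
  stopifnot(all(gridDim(grid) == nNew))
  state <- matrix(rep(tp06RestingState(), each = nNew^2), nNew^2, 19)
  idx <- as.vector(outer((pad + 1):(pad + nOld),
                         (pad + 1):(pad + nOld) - 1L,
                         function(r, c) r + nNew * c))
  state[idx, ] <- finalState(fr$recording)
  cfg <- simConfig(duration = duration, params = tp06Params("spiral"),
                   probes = probes)
  runTissue(grid, cfg, list(), init = state,
            t0 = max(frameTimes(fr$recording)))
}

# Rotor anchored on a scar: a solid 3.2 cm necrotic core with a 25%
# diffuse-fibrosis border zone out to 5.6 cm, imposed under the mature
# free rotor at its meander center.  The wave pins into anatomical
# re-entry around the scar (slow path along the fibrotic border).
sharedPinnedRotor <- function()
  sharedRun("pinnedRotor", function() {
    fr <- sharedFreeRotor()
    nn <- 240L
    tr <- fr$tipTrack
    ctr <- round(meanTip(tr, 800, max(tr$time)))
    rNodes <- 5.6 / 2 / 0.025
    ctr <- pmin(pmax(ctr, rNodes + 2), nn - rNodes - 2)
    core <- makeFibrosisMap(scarSpec(ctr, 3.2, "uniform", 100),
                            c(nn, nn))
    rim <- makeFibrosisMap(scarSpec(ctr, 5.6, "uniform", 25),
                           c(nn, nn))
    grid <- tissueGrid(pmax(fibrosisPct(core), fibrosisPct(rim)),
                       seed = 9L)
    spec <- scarSpec(ctr, 5.6, "uniform", 25)
    rec <- continueWithScar(fr, grid, duration = 900,
                            probes = rbind(probeRing(ctr, 3.3, 16, grid),
                                           probeRing(ctr, 2.5, 8, grid)))
    list(recording = rec, spec = spec)
  })

# Necrotic-only control: a small solid disk (no fibrotic border, no
# remodeling) far from the mature rotor; the rotor must ignore it.
sharedNecroticControl <- function()
  sharedRun("necroticControl", function() {
    fr <- sharedFreeRotor()
    spec <- scarSpec(c(120, 204), 1.6, "uniform", 50)
    grid <- makeControls(spec, c(240, 240))$necrotic_only
    ctr0 <- meanTip(fr$tipTrack, max(fr$tipTrack$time) - 600,
                    max(fr$tipTrack$time))
    rec <- continueWithScar(fr, grid, duration = 500,
                            probes = rbind(probeRing(spec@center, 1.4, 12,
                                                     grid),
                                           probeRing(round(ctr0), 1.2, 6,
                                                     grid)))
    list(recording = rec, spec = spec, center0 = ctr0)
  })
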