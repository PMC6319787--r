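# rotoranchor

Rotor dynamics and dynamical anchoring in 2D fibrotic human ventricular
tissue.

Re-entrant rotors drive many ventricular and atrial tachyarrhythmias,
and they are conspicuously found sitting on fibrotic scars.
`rotoranchor` is an R package for the in-silico side of that question:
it simulates two-dimensional sheets of human ventricular myocytes (the
ten Tusscher–Panfilov 2006 ionic model) coupled by discrete gap
junctions, with fibrosis represented as randomly placed electrically
uncoupled, unexcitable nodes, and provides the protocols and analysis
tools needed to study how a fibrotic scar restructures and eventually
anchors a rotor initiated far away from it: S1S2 cross-field rotor
initiation, conduction-velocity and conduction-block measurements,
phase-singularity detection and tracking, outcome classification
(terminated / anchored single or multi-armed / not anchored), and a
dipole-source pseudo-ECG.

## The model in one paragraph

Tissue is a rectangular lattice of nodes, 250 µm apart, each a TP06
myocyte.  Voltage evolves by the discrete monodomain equation

    C_m dV_ik/dt = sum_nb eta * g_gap * (V_nb − V_ik) − I_ion(V_ik, …)

with `g_gap = 103.6 nS` and 4-neighbor coupling; uncoupled edges are
no-flux.  The node capacitance is calibrated once so a planar wave paced
at cycle length 1000 ms travels at 72 cm/s.  A fibrosis-percentage field
`f(x) ∈ [0,100]` makes each node an obstacle with probability `f/100`
(seeded, reproducible textures); above ≈41% the myocyte lattice stops
percolating and the region behaves as solid scar.  Fibrotic myocytes may
additionally carry ionic remodeling: `G_Na`, `G_Kr`, `G_Ks` scaled by
`1 − 1.55 f/100`, `1 − 1.75 f/100`, `1 − 2 f/100` (62% / 70% / 80%
reductions at `f = 40%`).  Integration is forward Euler at `dt = 0.02 ms`
with Rush–Larsen gate updates, implemented in C++.

See `vignettes/rotoranchor-methods.Rmd` for the full account of the
model, the numerics and the design decisions.

## A worked example

Measure the conduction velocity of a paced planar wave, then the effect
of 30% diffuse fibrosis:

```r
library(rotoranchor)

cv0 <- measureCV(level = 0, cl = 1000, dims = c(240, 10),
                 probeRows = c(60, 160), conditioningBeats = 1)
cv0$cv
#> [1] 72.00461

cv30 <- measureCV(level = 30, cl = 1000, seeds = 1:3, dims = c(240, 48),
                  probeRows = c(60, 140), conditioningBeats = 1,
                  pacedInit = TRUE)
round(c(cv30$cv, cv30$sd), 2)
#> [1] 47.66  1.24
```

A healthy sheet conducts at ≈72 cm/s; scattering 30% unexcitable nodes
through it slows the wave to ≈48 cm/s because the front percolates
through a partly blocked lattice.  Raising the level past ≈41% blocks
conduction altogether:

```r
bt <- blockThreshold(levels = 38:46, seeds = 1:5, dims = c(200, 72),
                     bandRows = 41:180)
bt$threshold
#> [1] 41
```

Build a synthetic scar and classify a run (heavier; minutes):

```r
sg  <- makeScarGrid(c(256, 512), diameter = 6.4, level = 50, seed = 1)
cfg <- simConfig(duration = 20000, params = tp06Params(),
                 probes = probeRing(sg$spec@center, 4.2, 16, sg$grid))
ini <- initiateRotor(sg$grid, cfg, s1s2Spec(c(128, 160)))
rec <- runTissue(sg$grid, cfg, list(), init = ini$state, t0 = ini$endTime)
classifyOutcome(rec, sg$spec)
```

`runDistanceSweep()`, `runAnchorTime()` and `runPhaseDiagram()` drive
the full anchoring experiments (outcome versus rotor–scar distance,
anchoring-time regression, and the scar-size × fibrosis-level phase
diagram); all accept `fullScale = TRUE` for full-size runs.

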