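---
title: "Modeling rotor dynamics around fibrotic scars: methods and design"
author: "rotoranchor maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling rotor dynamics around fibrotic scars: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(rotoranchor)
```

## The model

rotoranchor simulates two-dimensional human ventricular tissue as a
rectangular lattice of excitable nodes coupled by discrete gap
junctions.  Each node carries the ten Tusscher–Panfilov 2006 (TP06)
ionic model of the human ventricular myocyte — 19 state variables: the
transmembrane voltage $V$, ten voltage-dependent Hodgkin–Huxley gates,
the calcium-subspace gate, the ryanodine-receptor adaptation variable,
and intracellular Na$^+$, K$^+$ and three-compartment Ca$^{2+}$
concentrations.  The voltage of node $(i,k)$ obeys the discrete
monodomain equation

$$C_m \frac{dV_{ik}}{dt} \;=\; \sum_{\text{neighbors}} \eta\,
  g_{\text{gap}} \left( V_{\text{nb}} - V_{ik} \right) \;-\;
  I_{\text{ion}}(V_{ik}, \ldots),$$

where $\eta \in \{0, 1\}$ is the connectivity indicator,
$g_{\text{gap}} = 103.6$ nS is the gap-junction conductance, and
$I_{\text{ion}}$ is the total TP06 membrane current.  Nodes are
$250\ \mu\mathrm{m} \times 250\ \mu\mathrm{m}$; every myocyte couples to
the 4 von Neumann neighbors that are myocytes.  Uncoupled edges — at
the domain boundary and wherever a neighbor is an obstacle — implement
no-flux conditions, so fibrosis and boundaries are treated uniformly.

### Diffuse fibrosis and the scar

Diffuse fibrosis is represented by electrically uncoupled, unexcitable
nodes: given a fibrosis-percentage field $f(x) \in [0, 100]$, each node
independently becomes an obstacle with probability $f/100$.  Textures
are drawn by comparing one seeded per-node uniform field against
$f/100$, which makes them reproducible per seed and pointwise monotone
in $f$ (raising the fibrosis level can only add obstacles).  The
synthetic scar emulates what a clinical late-gadolinium-enhancement
pipeline yields: a circular region whose fibrosis percentage either
falls linearly from a peak at the center to 0 at the rim (a compact
core with a graded border zone) or is uniform.  Above roughly 41%
fibrosis the surviving-myocyte lattice stops percolating — site
percolation on the square lattice fails once the open fraction drops
below $\approx 0.593$ — and the region behaves as a solid inexcitable
scar, which is why the >41% core of the graded scar acts as the
necrotic center.

### Ionic remodeling

Fibrotic regions may additionally carry ionic remodeling of the
surviving myocytes.  The peak conductances of $I_{\mathrm{Na}}$,
$I_{\mathrm{Kr}}$ and $I_{\mathrm{Ks}}$ are scaled by
$1 - 1.55 f/100$, $1 - 1.75 f/100$ and $1 - 2 f/100$ respectively
(clamped at 0; at $f = 40\%$ the reductions are 62%, 70% and 80%).
This prolongs the action potential inside the fibrotic region, which is
one of the mechanisms by which the border zone seeds wavebreaks.

## Numerics

* **Time stepping.** Voltage and concentrations advance by forward
  Euler with $dt = 0.02$ ms.  The Hodgkin–Huxley gates advance by
  Rush–Larsen exponential updates,
  $g \leftarrow g_\infty - (g_\infty - g)\,e^{-dt/\tau_g}$: the TP06
  activation gate of $I_{\mathrm{Na}}$ has $\tau_m \approx 1\ \mu$s at
  depolarized potentials, so a forward-Euler gate update is
  unconditionally unstable at any practical $dt$; Rush–Larsen is the
  standard choice for this model and is unconditionally stable for the
  gate subsystem.  A run at $dt = 0.002$ ms changes the paced action
  potential by well under 1 mV (see the test suite).
* **Lookup tables.** All voltage-dependent rate and current factors are
  tabulated on a 0.05 mV grid over $[-110, 90]$ mV and linearly
  interpolated, keeping the inner loop free of exponentials.  Reversal
  potentials are refreshed every 25 steps (0.5 ms); concentrations
  drift far too slowly for this to matter at double precision (the
  measured planar CV is unchanged to five digits up to a 1 ms refresh).
* **Units.** TP06 currents are per-capacitance (pA/pF).  The coupling
  term is folded into the same normalization through the node
  capacitance $C_m$, giving a coupling rate
  $c = g_{\text{gap}}/C_m$ in ms$^{-1}$.  $C_m$ is not observable from
  the model outputs directly and was calibrated once per parameter
  variant, by bisection, so that a planar wave paced at cycle length
  1000 ms travels at 72 cm/s ($C_m = 43.35$ pF for the epicardial set,
  27.75 pF for the re-entry variant).  Each parameter vector carries its
  calibrated value as an attribute and the value is not revisited per
  experiment.
* **Quiescence tiling.** Bands of 16 rows sleep — their state is frozen
  and they exchange no current — once the band and both neighbor bands
  have moved by less than $5\times10^{-4}$ mV/ms for 5 ms
  and no stimulus targets them; any neighbor activity or stimulus wakes
  them.  This skips the electrically silent diastole between paced
  beats.  The threshold is far below any physiological rate of change
  (the resting-state drift of the published TP06 initial conditions is
  $\sim 2\times10^{-4}$ mV/ms), and the 5 ms persistence requirement
  prevents freezing at turning points of $V$.  The approximation is
  absent from exactness-sensitive test modes (`zeroIon`), and the
  conduction-velocity calibration was performed with tiling active, so
  the calibration surface matches production runs.
* **Determinism.** A run is a pure function of (grid, config, stimuli,
  initial state); textures are pure functions of (fibrosis map, seed).
  Identical inputs give bit-identical recordings on the same platform.

## Protocols

* **Stimulus strength.** All pacing protocols stimulate at twice
  the diastolic threshold for 2 ms.  The threshold is found once per
  parameter set by bisection on a single cell and cached.
* **Conduction velocity.** A thin strip is paced at one edge; the CV is
  the probe-row distance (≥ 2 cm) divided by the activation-time
  difference (first upstroke crossing of −20 mV, resolved at the
  integration step) of a beat following the conditioning beats.  For
  fibrotic strips one obstacle texture is drawn per seed and the CV is
  averaged over seeds; a wave that never reaches the distal probe row
  is recorded as blocked, an outcome rather than an error.
* **Conduction-block threshold.** A single planar wave is sent at a
  patch whose central band carries uniform fibrosis, for each level ×
  seed; the threshold is the lowest level at which no seed crosses.
* **S1S2 rotor initiation.** A planar S1 wave travels down the sheet;
  when its repolarization tail (falling crossing of −60 mV) passes the
  intended tip position, an S2 covering the half-plane of columns to
  one side of the tip is delivered.  The broken S2 front curls into a
  single rotor; the protocol verifies exactly one phase singularity and
  raises a protocol-failure error (with a diagnostic voltage frame)
  otherwise.  Mirroring the S2 half-plane flips the rotor chirality.
  In compact sheets the S1 stage is delivered as a short train (two
  beats at 340 ms) rather than a single beat: restitution then
  shortens the action potential during the rotor's first turns, which
  keeps the young spiral's wavelength inside the domain.  This is a
  standard cross-field variant; in large domains a single S1 behaves
  identically.

## Rotor analysis

* **Phase singularities.** The phase is a time-delay embedding,
  $\theta = \mathrm{atan2}(V(t) - V^*,\ V(t - \tau) - V^*)$ with
  $\tau = 20$ ms and $V^* = -40$ mV.  A singularity is a grid plaquette
  around which the winding number of $\theta$ is $\pm 2\pi$; the sign
  is the topological charge, positive meaning counter-clockwise in
  grid coordinates (row index increasing downward).  The production
  detector is verified against a brute-force winding-number oracle on
  every test frame.  Plaquettes touching obstacles are skipped (phase
  is undefined there), so singularities inside dense fibrosis are only
  reported at texture-free plaquettes — a documented limitation.
* **Period.** The period of the activation pattern is the median
  inter-activation interval (−20 mV upcrossings) pooled over probes in
  a 320 ms window.  Probes are placed on a 16-point ring 1 cm outside
  the scar rim — an anchored rotor's period is set at the scar — plus
  4 far-field probes so a free rotor's period is observable too.  A
  probe with no activation in the window contributes the window length
  (right-censored); a probe with one activation contributes nothing.
* **Classification.**  At the classification time the pattern is
  *terminated* if every myocyte is below −20 mV; otherwise *anchored*
  if the period exceeds 280 ms over the 320 ms window (anchored
  rotation around the scar is slow anatomical re-entry; a free rotor
  turns near 222 ms); anchored patterns are subdivided by the count of
  same-sign singularities within a 1 cm annulus of the scar rim
  (single CW, single CCW, multi-armed).  Everything else is
  *not-anchored*.  The time-to-anchor is the earliest time from which
  the criterion holds continuously to the end of the run; transient
  excursions are ignored.

## Pseudo-ECG

The far-field electrogram is the dipole-density sum
$\mathrm{ECG}(t) = \sum_i (\vec r_i \cdot D \nabla V_i)\, /\, |\vec r_i|^3\, dA$
over myocyte nodes, with $\nabla V$ by central differences (one-sided
at obstacles and boundaries) and the electrode 10 cm above the sheet
center.  $D$ is the scalar effective diffusion implied by the discrete
coupling, $D = g_{\text{gap}}\,dx^2 / C_m$; only relative units are
meaningful and no absolute calibration is attempted.  Beat features
(cycle lengths; amplitude variability as the coefficient of variation
of peak amplitudes in a sliding 5-beat window) distinguish
monomorphic from polymorphic patterns: anchoring converts an irregular,
polymorphic trace into a slower, regular one.

## Parameter variants

`tp06Params("epi")` is the published epicardial set, used for every
conduction-velocity and conduction-block measurement; its calibrated
node capacitance is 43.35 pF.  The re-entry studies use
`tp06Params("spiral")`, a reduced-wavelength variant: peak sodium
conductance halved (the coupling recalibrated to $C_m = 27.7$ pF so the
planar CV at 1 Hz stays 72 cm/s), the $I_{\mathrm{CaL}}$
voltage-inactivation time constant scaled by 0.6, and sodium-channel
recovery from inactivation accelerated two-fold below −40 mV.  The
variant shortens the paced APD$_{90}$ from ≈ 293 to ≈ 240 ms and
reduces both the rotor core size and the re-entry wavelength, so that
an S1S2 rotor is sustained in a 6 cm sheet.

The reason for the variant is quantitative and worth stating plainly:
with the published epicardial set the re-entry wavelength
(CV × APD ≈ 10–13 cm) exceeds any desk-tractable sheet.  In sheets of
6–8 cm the young spiral saturates the tissue (≈ 80% depolarized within
two turns) and self-terminates; sustaining it needs sheets comparable
to the ≈ 25 × 13 cm domains of the source studies.  In the stable
desk-scale regime the free rotor rotates at ≈ 198–212 ms depending on
the measurement window — about 10% below the ≈ 222 ms the full-scale
model produces.  The search over
restitution and excitability parameters (sodium and potassium
conductance scalings, inactivation-recovery scalings, S2 geometry and
timing) showed the rotation rate to be core-dynamics-limited: every
change that lengthened the period also lengthened the wavelength and
destabilized the rotor at this domain size.  The 280 ms anchoring
bound still separates the free-rotor period (≈ 199 ms) cleanly from
anchored rotation (> 280 ms), so the classification machinery is
unaffected; the absolute free-rotor period should be read as a
desk-scale approximation.

## Problem sizes

The full-scale experiments of the source studies (1024 × 512 nodes,
40 s of activity, hundreds of textures per condition) are
cluster-scale.  The package defaults are desk-scale and every driver
accepts `fullScale = TRUE` to restore the full domain and duration.
Sizes used by the bundled acceptance/verification runs, chosen as the
smallest that keep each measurement physically meaningful:

* homogeneous CV: 400 × 24 strip, 2 conditioning beats at CL 1000 ms;
* fibrotic CV (30%): 240 × 48 strip, 10 texture seeds, probes 2 cm
  apart, one tissue conditioning beat on top of a 1 Hz-paced initial
  state;
* block threshold: 200 × 72 patch with a 3.5 cm fibrotic band,
  levels 36–48% in 1% steps, 10 seeds each (short bands near the
  percolation threshold are crossed by finite-size fluctuation paths and
  read high; 3.5 cm is the smallest band we found that approaches the
  bulk behavior);
* free-rotor period: 240 × 240 sheet (6 cm), S1 pair + S2, ≈ 1.8 s of
  activity, period over the final 0.9 s;
* controls and anchored-rotor checks: continuations of the free-rotor
  run (below).

Because S1S2 initiation with a scar already present fails at this
domain scale (the scar perturbs the marginal initiation), the anchored
and control reference configurations are built as continuations: the
tissue grid is swapped under the mature rotating wave.  Imposing a
3.2 cm solid core with a 25% fibrotic border zone out to 5.6 cm at the
rotor's meander center pins the wave into anatomical re-entry
(period ≈ 286 ms, classified anchored); imposing a small distant solid
disk leaves the rotor unaffected (not anchored, tip drift well under
1 cm) — the necrotic-only control.

What the synthetic generator does *not* emulate: anisotropy and fiber
rotation, patchy/interstitial fibrosis textures, 3-D transmural
structure, and MRI-derived irregular scar geometry.  Passing tests
demonstrate correct implementation of the stated model — not that the
model reproduces any particular patient's arrhythmia.

## Known limitations

* The phase-singularity detector reports no singularities inside dense
  obstacle clusters (phase undefined on obstacles).
* Multi-arm counting is automated (same-sign singularities in the rim
  annulus); visual adjudication of exotic patterns is out of scope.
* The pseudo-ECG is relative; no torso volume conductor is modeled.
* Single precision is not offered; all arithmetic is double precision.
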