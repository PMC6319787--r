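#' TP06 ventricular myocyte parameters
#'
#' Returns the full named parameter vector of the ten Tusscher-Panfilov
#' 2006 human ventricular cell model.  The default is the epicardial
#' variant.  Individual entries can be overridden through `...`, which is
#' how restitution variants (e.g. scaled inactivation time constants or
#' potassium conductances) are expressed.
#'
#' Units follow the TP06 convention: conductances in nS/pF, permeabilities
#' in cm/ms (per capacitance), concentrations in mM, time in ms, voltage
#' in mV.  All membrane currents evaluate to pA/pF.
#'
#' @param variant Parameter set tag. `"epi"` is the published epicardial
#'   set; `"spiral"` is the reduced-wavelength re-entry variant used for
#'   rotor studies in compact sheets: peak sodium conductance halved
#'   (with the gap-junction coupling recalibrated so the planar CV at
#'   1 Hz stays 72 cm/s), the L-type calcium inactivation time constant
#'   scaled by 0.6 (`tauf_scale`), and sodium-channel recovery from
#'   inactivation accelerated two-fold below -40 mV
#'   (`tauhj_rec_scale`).  The variant shortens the action potential
#'   (APD90 about 240 ms) and the post-repolarization refractoriness so
#'   that an S1S2 rotor is sustained in a 6 cm sheet, where it rotates
#'   with a period near 200 ms; see the methods vignette for why the
#'   published epicardial set cannot sustain a free rotor at this
#'   domain scale.
#' @param ... Named numeric overrides applied on top of the variant.
#' @return Named numeric vector of model constants, with attributes
#'   `variant` and `cmNode` (the coupling-calibrated node capacitance in
#'   pF for this variant).
#' @examples
#' p <- tp06Params()
#' p[["GNa"]]
#' @export
tp06Params <- function(variant = c("spiral", "epi"), ...) {
  variant <- match.arg(variant)
  p <- c(
    Rgas = 8314.472, Temp = 310, Faraday = 96485.3415,
    Cap = 0.185, Vc = 0.016404, Vsr = 0.001094, Vss = 5.468e-5,
    Ko = 5.4, Nao = 140, Cao = 2, pKNa = 0.03,
    GNa = 14.838, GK1 = 5.405, Gto = 0.294, GKr = 0.153, GKs = 0.392,
    GCaL = 3.98e-5, GbNa = 2.9e-4, GbCa = 5.92e-4, GpCa = 0.1238,
    GpK = 0.0146,
    PNaK = 2.724, KmK = 1, KmNa = 40,
    kNaCa = 1000, KmNai = 87.5, KmCa = 1.38, ksat = 0.1, gamma = 0.35,
    KpCa = 5e-4, Vmaxup = 0.006375, Kup = 2.5e-4,
    Vrel = 0.102, Vleak = 3.6e-4, Vxfer = 0.0038,
    k1p = 0.15, k2p = 0.045, k3 = 0.06, k4 = 0.005,
    maxsr = 2.5, minsr = 1, EC = 1.5,
    Bufc = 0.2, Kbufc = 0.001, Bufsr = 10, Kbufsr = 0.3,
    Bufss = 0.4, Kbufss = 2.5e-4,
    tauf_scale = 1, taus_scale = 1, tauhj_rec_scale = 1
  )
  if (variant == "spiral") {
    p[["GNa"]] <- p[["GNa"]] * 0.5
    p[["tauf_scale"]] <- 0.6
    p[["tauhj_rec_scale"]] <- 0.5
  }
  dots <- c(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(names(dots) == ""))
      stop("overrides must be named")
    unknown <- setdiff(names(dots), names(p))
    if (length(unknown))
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
    p[names(dots)] <- dots
  }
  if (any(p[grep("^G", names(p))] < 0))
    stop("conductances must be non-negative")
  # per-variant node capacitance calibrated to 72 cm/s planar CV at
  # CL 1000 ms (g_gap = 103.6 nS, dx = 250 um, dt = 0.02 ms)
  cm <- if (variant == "spiral") ra_spiral_cm_node else ra_default_cm_node
  structure(p, variant = variant, cmNode = cm)
}

#' Fibrosis-dependent ionic remodeling factors
#'
#' Multiplicative scale factors applied to the peak conductances of
#' I_Na, I_Kr and I_Ks as a function of the local fibrosis percentage f:
#' \deqn{s_{Na} = 1 - 1.55 f/100,\quad s_{Kr} = 1 - 1.75 f/100,\quad
#'       s_{Ks} = 1 - 2 f/100,}
#' each clamped below at zero (the linear formulas go negative for
#' f > 64.5\%, 57.1\% and 50\% respectively; a conductance cannot be
#' negative, and nodes at such fibrosis levels are mostly obstacles
#' anyway).  At f = 40\% this gives reductions of 62\%, 70\% and 80\%.
#'
#' @param f Local fibrosis level(s) in percent, in \[0, 100\].
#' @return Numeric matrix with one row per element of `f` and columns
#'   `sNa`, `sKr`, `sKs`, each in \[0, 1\].
#' @examples
#' remodelingFactors(40)   # 0.38, 0.30, 0.20
#' @export
remodelingFactors <- function(f) {
  if (!is.numeric(f) || any(!is.finite(f)) || any(f < 0) || any(f > 100))
    stop("fibrosis percentage must be within [0, 100]")
  cbind(sNa = pmax(0, 1 - 1.55 * f / 100),
        sKr = pmax(0, 1 - 1.75 * f / 100),
        sKs = pmax(0, 1 - 2 * f / 100))
}

#' Apply ionic remodeling to a parameter set
#'
#' Scales `GNa`, `GKr` and `GKs` of a TP06 parameter vector by the
#' remodeling factors at local fibrosis level `f`; all other parameters
#' are untouched.
#'
#' @param f Local fibrosis level in percent (scalar).
#' @param params TP06 parameter vector from [tp06Params()].
#' @return Parameter vector with scaled conductances.
#' @export
applyRemodeling <- function(f, params = tp06Params()) {
  stopifnot_scalar(f)
  s <- remodelingFactors(f)
  params[["GNa"]] <- params[["GNa"]] * s[1, "sNa"]
  params[["GKr"]] <- params[["GKr"]] * s[1, "sKr"]
  params[["GKs"]] <- params[["GKs"]] * s[1, "sKs"]
  params
}

#' TP06 resting state
#'
#' The quiescent steady state of the TP06 model used to initialize
#' simulations (published resting values).
#'
#' @return Named numeric vector of the 19 state variables; `V` in mV,
#'   gates dimensionless, concentrations in mM.
#' @export
tp06RestingState <- function() {
  c(V = -86.2, m = 0, h = 0.75, j = 0.75, xr1 = 0, xr2 = 1, xs = 0,
    r = 0, s = 1, d = 0, f = 1, f2 = 1, fcass = 1, rr = 1,
    cai = 7e-5, casr = 1.3, cass = 7e-5, nai = 7.67, ki = 138.3)
}

#' Names of the TP06 state variables
#' @return Character vector of length 19 in integrator column order.
#' @export
tp06StateNames <- function() as.character(.tp06_state_names())

#' TP06 time derivatives at a state point
#'
#' Evaluates the full right-hand side of the single-cell TP06 model
#' (total ionic current folded into dV/dt, plus the derivatives of all
#' gates and concentrations).  A non-finite state input is rejected with
#' the offending variable named.
#'
#' @param state Named numeric state vector (see [tp06RestingState()]).
#' @param params Parameter vector from [tp06Params()].
#' @param istim Stimulus current (pA/pF); negative values depolarize.
#' @return Named vector of time derivatives (per ms).
#' @export
tp06Derivs <- function(state, params = tp06Params(), istim = 0) {
  .tp06_derivs_cpp(as.numeric(state[tp06StateNames()]), params, istim)
}
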