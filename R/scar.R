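# Synthetic fibrotic-scar generation: fibrosis-percentage fields,
# seeded obstacle textures and control geometries.  These emulate what a
# clinical pipeline derives from LGE-MRI signal intensity: a normalized
# intensity map is read as a local fibrosis percentage, the >41% core
# behaving as inexcitable scar.

#' Build a fibrosis-percentage map for a circular scar
#'
#' Places a circular fibrotic region on an otherwise healthy grid.  With
#' the `radial_linear` profile the fibrosis percentage falls linearly
#' from `level` at the scar center to 0 at the rim (the configuration
#' with a 6.4 cm diameter and 50% center emulates a compact post-infarct
#' scar with a graded border zone); with `uniform` it is constant inside
#' the disk.  Distances are measured in physical units from node centers;
#' nodes at exactly the rim get f = 0.
#'
#' @param spec A [ScarSpec-class].
#' @param dims Grid dimensions (rows, cols).
#' @param spacing Node spacing in cm (250 um default).
#' @return A [FibrosisMap-class].
#' @examples
#' m <- makeFibrosisMap(scarSpec(c(64, 64), 3.2), c(128, 128))
#' max(fibrosisPct(m))
#' @export
makeFibrosisMap <- function(spec, dims, spacing = 0.025) {
  stopifnot(is(spec, "ScarSpec"))
  validObject(spec)
  radius <- spec@diameter / 2
  lo <- (spec@center - 1) * spacing
  hi <- (dims - spec@center) * spacing
  if (any(c(lo, hi) < radius - spacing))
    stop("scar does not fit inside the grid")
  rr <- (seq_len(dims[1]) - spec@center[1]) * spacing
  cc <- (seq_len(dims[2]) - spec@center[2]) * spacing
  dist <- sqrt(outer(rr^2, cc^2, `+`))
  pct <- matrix(0, dims[1], dims[2])
  inside <- dist < radius
  pct[inside] <- if (spec@profile == "radial_linear")
    spec@level * (1 - dist[inside] / radius) else spec@level
  new("FibrosisMap", pct = pct, spacing = spacing)
}

#' Draw one obstacle texture from a fibrosis map
#'
#' Each node independently becomes an electrically uncoupled unexcitable
#' obstacle with probability f/100 (its local fibrosis percentage).  The
#' construction compares a single seeded per-node uniform field against
#' f/100, so for a fixed seed the texture is reproducible and pointwise
#' monotone: raising f anywhere can only add obstacles.
#'
#' @param map A [FibrosisMap-class] (or percentage matrix).
#' @param seed Integer seed of the uniform field.
#' @param spacing Spacing when `map` is a plain matrix.
#' @return An [ObstacleTexture-class].
#' @export
sampleTexture <- function(map, seed = 1L, spacing = 0.025) {
  if (is.matrix(map)) map <- new("FibrosisMap", pct = map, spacing = spacing)
  validObject(map)
  u <- withSeed(seed, matrix(runif(length(map@pct)), nrow(map@pct)))
  new("ObstacleTexture", mask = u < map@pct / 100,
      seed = as.integer(seed), mapHash = raHash(map@pct))
}

#' Control geometries: no scar and necrotic-only scar
#'
#' Builds the two control tissues used alongside a fibrotic scar: a
#' homogeneous sheet with no obstacles at all (`no_scar`) and a sheet
#' where every node inside the scar disk is an obstacle with no
#' surrounding partial fibrosis and no remodeling field
#' (`necrotic_only`).
#'
#' @param spec A [ScarSpec-class] giving center and diameter.
#' @param dims Grid dimensions (rows, cols).
#' @param spacing Node spacing in cm.
#' @return Named list of two [TissueGrid-class] objects, `no_scar` and
#'   `necrotic_only`.
#' @export
makeControls <- function(spec, dims, spacing = 0.025) {
  zero <- new("FibrosisMap", pct = matrix(0, dims[1], dims[2]),
              spacing = spacing)
  no_scar <- new("TissueGrid", fibrosis = zero,
                 obstacles = new("ObstacleTexture",
                                 mask = matrix(FALSE, dims[1], dims[2]),
                                 seed = 0L, mapHash = raHash(zero@pct)))
  solid <- makeFibrosisMap(scarSpec(spec@center, spec@diameter,
                                    "uniform", 100),
                           dims, spacing)
  mask <- solid@pct >= 100
  necrotic <- new("TissueGrid", fibrosis = zero,
                  obstacles = new("ObstacleTexture", mask = mask, seed = 0L,
                                  mapHash = raHash(zero@pct)))
  list(no_scar = no_scar, necrotic_only = necrotic)
}

#' Place a scar grid with a rotor-initiation margin
#'
#' Convenience builder used by the experiment drivers: a circular scar
#' centered `scarCol` columns from the right edge, with the remaining
#' tissue to the left free for rotor initiation.
#'
#' @param dims Grid dimensions (rows, cols).
#' @param diameter Scar diameter (cm).
#' @param profile,level Passed to [scarSpec()].
#' @param seed Texture seed.
#' @param spacing Node spacing (cm).
#' @param scarCenter Optional (row, col); default centers the scar
#'   vertically, one radius plus a small margin from the right edge.
#' @return List with elements `grid` ([TissueGrid-class]) and `spec`
#'   ([ScarSpec-class]).
#' @export
makeScarGrid <- function(dims, diameter = 6.4, profile = "radial_linear",
                         level = 50, seed = 1L, spacing = 0.025,
                         scarCenter = NULL) {
  radiusNodes <- diameter / 2 / spacing
  if (is.null(scarCenter))
    scarCenter <- c(dims[1] / 2, dims[2] - radiusNodes - 8)
  spec <- scarSpec(scarCenter, diameter, profile, level)
  map <- makeFibrosisMap(spec, dims, spacing)
  list(grid = tissueGrid(map, seed = seed), spec = spec)
}
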