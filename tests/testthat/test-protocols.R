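# Stimulation protocols: thresholds, CV measurement, S1S2 initiation.

test_that("diastolic threshold is found, cached, and plausible", {
  prm <- tp06Params("epi")
  thr <- diastolicThreshold(prm)
  expect_gt(thr, 2); expect_lt(thr, 60)
  # sub-threshold fails, supra-threshold fires
  lo <- singleCellRun(prm, duration = 60, stimTimes = 5,
                      amplitude = 0.45 * thr)
  hi <- singleCellRun(prm, duration = 60, stimTimes = 5,
                      amplitude = 2 * thr)
  expect_lt(max(lo$V), 0)
  expect_gt(max(hi$V), 0)
  expect_identical(diastolicThreshold(prm), thr)  # cache hit
})

test_that("fibrotic strips slow conduction monotonically and can block", {
  cv0 <- measureCV(level = 0, dims = c(200, 10), probeRows = c(50, 140),
                   conditioningBeats = 0)
  cv20 <- measureCV(level = 20, seeds = 1:2, dims = c(200, 48),
                    probeRows = c(50, 140), conditioningBeats = 0)
  expect_lt(cv20$cv, cv0$cv)
  # far above the percolation threshold the wave cannot cross
  cv60 <- measureCV(level = 60, seeds = 1:2, dims = c(200, 48),
                    probeRows = c(50, 140), conditioningBeats = 0)
  expect_equal(cv60$blockedFraction, 1)
  expect_true(is.na(cv60$cv))
})

test_that("S1S2 in homogeneous tissue creates exactly one rotor that flips
           chirality when the S2 half-plane is mirrored", {
  dims <- c(200, 200)
  grid <- tissueGrid(matrix(0, dims[1], dims[2]))
  cfg <- simConfig(duration = 0)
  tip <- c(110, 100)
  ini <- initiateRotor(grid, cfg, s1s2Spec(tip), settle = 150)
  expect_equal(nrow(ini$tip), 1)
  # mirrored S2: stimulate the columns on the other side of the tip
  mir <- s1s2Spec(tip, s2Cols = 100:200)
  ini2 <- initiateRotor(grid, cfg, mir, settle = 150)
  expect_equal(nrow(ini2$tip), 1)
  expect_equal(ini$tip$charge, -ini2$tip$charge)
})

test_that("S2 after full recovery produces a plane wave, not a rotor", {
  dims <- c(100, 60)
  grid <- tissueGrid(matrix(0, dims[1], dims[2]))
  amp <- 2 * diastolicThreshold(tp06Params())
  cfg1 <- simConfig(duration = 600, frameStride = 10)
  rec1 <- runTissue(grid, cfg1,
                    list(edgeStimulus(dims, rows = 1:3, amplitude = amp)))
  # everything is repolarized by 600 ms; S2 now excites the half plane
  s2 <- matrix(FALSE, dims[1], dims[2]); s2[, 1:30] <- TRUE
  cfg2 <- simConfig(duration = 180, frameStride = 10)
  rec2 <- runTissue(grid, cfg2,
                    list(stimulusSpec(s2, start = 600, amplitude = amp)),
                    init = finalState(rec1), t0 = 600)
  ps <- detectSingularities(rec2, 690)
  expect_equal(nrow(ps), 0)
})

test_that("probe rings avoid obstacles and stay inside the grid", {
  fib <- matrix(0, 60, 60); fib[20:40, 20:40] <- 100
  grid <- tissueGrid(fib, seed = 2)
  ring <- probeRing(c(30, 30), radiusCm = 0.45, n = 12, grid = grid)
  expect_true(nrow(ring) >= 10)
  expect_true(all(!obstacleMask(grid)[ring]))
})
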