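# Discrete tissue integration: connectivity, conservation, oracles.

test_that("interior myocytes couple to 4 neighbors, edges and corners fewer", {
  conn <- buildConnectivity(matrix(FALSE, 6, 6))
  expect_equal(conn$count[3, 3], 4)
  expect_equal(conn$count[1, 3], 3)
  expect_equal(conn$count[1, 1], 2)
})

test_that("connectivity is symmetric and zero through obstacles", {
  obst <- matrix(FALSE, 8, 8)
  obst[4, 4] <- obst[4, 5] <- TRUE
  conn <- buildConnectivity(obst)
  nb <- conn$neighbors
  # symmetry: a coupled to b implies b coupled to a
  for (i in seq_len(nrow(nb)))
    for (j in nb[i, ][!is.na(nb[i, ])])
      expect_true(i %in% nb[j, ])
  # no edge touches an obstacle
  expect_true(all(is.na(nb[which(obst), ])))
  expect_false(any(which(obst) %in% nb[!is.na(nb)]))
})

test_that("a myocyte surrounded by obstacles has zero couplings", {
  obst <- matrix(FALSE, 5, 5)
  obst[2:4, 2:4] <- TRUE
  obst[3, 3] <- FALSE
  conn <- buildConnectivity(obst)
  expect_equal(conn$count[3, 3], 0)
})

test_that("checkerboard obstacles remove every coupling", {
  obst <- outer(1:6, 1:6, function(r, c) (r + c) %% 2 == 0)
  conn <- buildConnectivity(obst)
  expect_true(all(conn$count[!obst] == 0))
})

test_that("uniform resting tissue has an exactly zero coupling term", {
  grid <- tissueGrid(matrix(0, 10, 10))
  cfg <- simConfig(duration = 1, frameStride = 0, probeStride = 1)
  rec <- runTissue(grid, cfg, list())
  # with no stimulus and uniform state, all nodes remain identical
  st <- finalState(rec)
  expect_equal(max(st[, 1]) - min(st[, 1]), 0)
})

test_that("diffusion-only mode conserves the spatial mean of V", {
  nr <- 16; nc <- 12
  grid <- tissueGrid(matrix(0, nr, nc))
  init <- matrix(rep(tp06RestingState(), each = nr * nc), nr * nc, 19)
  set.seed(42)
  init[, 1] <- runif(nr * nc, -80, 20)  # arbitrary V field
  cfg <- simConfig(duration = 20, frameStride = 0, probeStride = 1)
  rec <- runTissue(grid, cfg, list(), init = init, zeroIon = TRUE)
  expect_equal(mean(finalState(rec)[, 1]), mean(init[, 1]),
               tolerance = 1e-12)
  # and pairwise coupling currents cancel: variance must shrink
  expect_lt(var(finalState(rec)[, 1]), var(init[, 1]))
})

test_that("two-node coupling currents are equal and opposite", {
  grid <- tissueGrid(matrix(0, 1, 2))
  init <- matrix(rep(tp06RestingState(), each = 2), 2, 19)
  init[1, 1] <- -30; init[2, 1] <- -80
  cfg <- simConfig(duration = 0.02, frameStride = 0, probeStride = 1)
  rec <- runTissue(grid, cfg, list(), init = init, zeroIon = TRUE)
  dv <- finalState(rec)[, 1] - init[, 1]
  expect_equal(dv[1], -dv[2], tolerance = 1e-12)
  # magnitude = dt * g/Cm * (V2 - V1)
  cc <- cfg@gGap / cfg@cmNode
  expect_equal(dv[1], 0.02 * cc * (init[2, 1] - init[1, 1]),
               tolerance = 1e-12)
})

test_that("obstacle nodes carry no state updates and report no voltage", {
  obst <- matrix(FALSE, 12, 12); obst[5:7, 5:7] <- TRUE
  fib <- matrix(0, 12, 12); fib[5:7, 5:7] <- 100
  grid <- tissueGrid(fib, obstacles = new("ObstacleTexture", mask = obst,
                                          seed = 1L, mapHash = "x"))
  cfg <- simConfig(duration = 5, frameStride = 5, probeStride = 1)
  rec <- runTissue(grid, cfg,
                   list(edgeStimulus(c(12, 12), rows = 1:2, amplitude = 52)))
  vf <- voltageFrame(rec, 5)
  expect_true(all(is.na(vf[obst])))
  expect_true(all(!is.na(vf[!obst])))
})

test_that("20-node cable matches the dense-matrix reference integrator", {
  prm <- tp06Params("epi")
  n <- 20
  cfg <- simConfig(duration = 50, frameStride = 0, probeStride = 1,
                   params = prm, eStride = 1L)
  grid <- tissueGrid(matrix(0, n, 1))
  stim <- edgeStimulus(c(n, 1), rows = 1:2, start = 5, amplitude = 52)
  rec <- runTissue(grid, cfg, list(stim))
  ref <- oracleCable(n, prm, cfg@gGap / cfg@cmNode, 0.02, 2500,
                     stimNodes = 1:2, stimStart = 5, stimAmp = 52,
                     record = 50)
  expect_lt(max(abs(finalState(rec)[, 1] - ref$V)), 0.1)
  # full state agreement, not only voltage
  expect_lt(max(abs(finalState(rec)[, 15] - ref$state[, "cai"])), 1e-6)
})

test_that("runs are deterministic and duration-0 yields only the start frame", {
  grid <- tissueGrid(matrix(20, 16, 16), seed = 5)
  cfg <- simConfig(duration = 10, frameStride = 5, probeStride = 1,
                   probes = cbind(8, 8))
  stim <- list(edgeStimulus(c(16, 16), rows = 1:2, amplitude = 52))
  r1 <- runTissue(grid, cfg, stim)
  r2 <- runTissue(grid, cfg, stim)
  expect_identical(probeTraces(r1), probeTraces(r2))
  expect_identical(voltageFrames(r1), voltageFrames(r2))
  cfg0 <- simConfig(duration = 0, frameStride = 5)
  r0 <- runTissue(grid, cfg0, list())
  expect_equal(length(frameTimes(r0)), 1L)
})

test_that("planar S1 produces isochrones parallel to the stimulated edge", {
  dims <- c(120, 30)
  grid <- tissueGrid(matrix(0, dims[1], dims[2]))
  cfg <- simConfig(duration = 450, frameStride = 0, probeStride = 1)
  rec <- runTissue(grid, cfg,
                   list(edgeStimulus(dims, rows = 1:3, amplitude = 52)))
  at <- rec@actTime
  # within any row the activation time is constant across columns
  spread <- apply(at[10:110, ], 1, function(x) diff(range(x)))
  expect_lt(max(spread), 1e-9)
  # and strictly increasing down the strip
  expect_true(all(diff(at[10:110, 15]) > 0))
})
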