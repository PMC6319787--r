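# Dipole-source pseudo-ECG and beat features.

# tiny recording wrapper around prescribed frames
frameRecording <- function(frames, frameTimes, grid,
                           cfg = simConfig(duration = max(frameTimes))) {
  n <- prod(gridDim(grid))
  fr <- vapply(seq_along(frameTimes), function(k) as.vector(frames[[k]]),
               numeric(n))
  fr[as.vector(obstacleMask(grid)), ] <- NA_real_
  new("SimRecording", frames = fr, frameTimes = frameTimes,
      probes = matrix(numeric(0), 0, 0), probeTimes = numeric(0),
      probeIndex = matrix(numeric(0), 0, 2),
      ecg = numeric(0), ecgTimes = numeric(0),
      actTime = matrix(NA_real_, gridDim(grid)[1], gridDim(grid)[2]),
      finalState = matrix(rep(tp06RestingState(), each = n), n, 19),
      grid = grid, config = cfg, configHash = "fixture",
      stopReason = "completed", stopTime = NA_real_)
}

test_that("uniform voltage gives an identically zero ECG", {
  grid <- tissueGrid(matrix(0, 10, 10))
  rec <- frameRecording(list(matrix(-85, 10, 10), matrix(20, 10, 10)),
                        c(0, 10), grid)
  ecg <- computeECG(rec, ecgConfig(c(0.125, 0.125, 10)))
  expect_equal(ecg$amplitudes, c(0, 0))
})

test_that("the ECG is linear and sign-flips with the voltage field", {
  grid <- tissueGrid(matrix(0, 12, 12))
  set.seed(8)
  v <- matrix(runif(144, -85, 30), 12, 12)
  cfg <- ecgConfig(c(0.15, 0.15, 10))
  e1 <- computeECG(frameRecording(list(v), 0, grid), cfg)$amplitudes
  e2 <- computeECG(frameRecording(list(-v), 0, grid), cfg)$amplitudes
  e3 <- computeECG(frameRecording(list(2 * v), 0, grid), cfg)$amplitudes
  expect_equal(e2, -e1, tolerance = 1e-12)
  expect_equal(e3, 2 * e1, tolerance = 1e-12)
})

test_that("a localized step matches the direct-summation oracle", {
  obst <- matrix(FALSE, 10, 10); obst[7, 3] <- TRUE
  fib <- matrix(0, 10, 10); fib[7, 3] <- 100
  grid <- tissueGrid(fib, obstacles = new("ObstacleTexture", mask = obst,
                                          seed = 1L, mapHash = "x"))
  v <- matrix(-85, 10, 10); v[4:6, 4:6] <- 10
  rec <- frameRecording(list(v), 0, grid)
  cfg <- ecgConfig(c(0.1, 0.1, 10), diffusion = 0.00175)
  mine <- computeECG(rec, cfg)$amplitudes
  ref <- oracleEcg(v, obst, 0.025, c(0.1, 0.1, 10), 0.00175)
  expect_equal(mine, ref, tolerance = 1e-10)
})

test_that("far-field amplitude falls roughly as 1/r^2", {
  grid <- tissueGrid(matrix(0, 10, 10))
  # a wavefront-like half-plane step (net dipole moment does not cancel)
  v <- matrix(-85, 10, 10); v[1:5, ] <- 20
  rec <- frameRecording(list(v), 0, grid)
  # double the full electrode vector so the viewing angle is unchanged
  e1 <- c(5, 4, 8); e2 <- 2 * e1
  a1 <- computeECG(rec, ecgConfig(e1, diffusion = 1))$amplitudes
  a2 <- computeECG(rec, ecgConfig(e2, diffusion = 1))$amplitudes
  expect_equal(a1 / a2, 4, tolerance = 0.05)
})

test_that("the electrode must stay clear of the tissue", {
  grid <- tissueGrid(matrix(0, 10, 10))
  rec <- frameRecording(list(matrix(0, 10, 10)), 0, grid)
  expect_error(computeECG(rec, ecgConfig(c(0.1, 0.1, 0.2))), "1 cm")
})

test_that("beat features recover cycle lengths and amplitude variability", {
  tt <- seq(0, 3000, by = 2)
  saw <- ((tt %% 300) / 300)
  bf <- beatFeatures(tt, saw)
  expect_true(all(abs(bf$cycleLengths - 300) <= 2))
  expect_true(all(bf$variability < 0.02))
  # alternating amplitudes 1, 2 -> CV of (1, 2, 1, 2, 1)
  peaks <- seq(100, 2900, by = 300)
  amp <- rep(c(1, 2), length.out = length(peaks))
  v <- rep(0, length(tt))
  for (k in seq_along(peaks)) {
    sel <- abs(tt - peaks[k]) <= 20
    v[sel] <- amp[k] * (1 - abs(tt[sel] - peaks[k]) / 20)
  }
  bf2 <- beatFeatures(tt, v, prominence = 0.2)
  ref <- sd(c(1, 2, 1, 2, 1)) / mean(c(1, 2, 1, 2, 1))
  expect_equal(bf2$variability[1], ref, tolerance = 1e-6)
  expect_error(beatFeatures(tt, v * 0 + c(0, 1, rep(0, length(tt) - 2))),
               "3 beats")
})
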