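# TP06 cell model and fibrosis-dependent ionic remodeling.

test_that("remodeling factors follow the linear conductance reductions", {
  s40 <- remodelingFactors(40)
  expect_equal(as.vector(s40), c(0.38, 0.30, 0.20), tolerance = 1e-12)
  expect_equal(as.vector(remodelingFactors(0)), c(1, 1, 1))
  expect_equal(as.vector(remodelingFactors(50)), c(0.225, 0.125, 0))
  # clamped at zero beyond the roots of the linear formulas
  expect_true(all(remodelingFactors(80) >= 0))
  expect_error(remodelingFactors(140), "within")
  expect_error(remodelingFactors(-2), "within")
})

test_that("remodeling factors are non-increasing in f and bounded", {
  f <- seq(0, 100, by = 0.5)
  s <- remodelingFactors(f)
  expect_true(all(s >= 0 & s <= 1))
  expect_true(all(diff(s[, "sNa"]) <= 0))
  expect_true(all(diff(s[, "sKr"]) <= 0))
  expect_true(all(diff(s[, "sKs"]) <= 0))
})

test_that("applyRemodeling scales only the three target conductances", {
  base <- tp06Params("epi")
  mod <- applyRemodeling(40, base)
  expect_equal(mod[["GNa"]], base[["GNa"]] * 0.38)
  expect_equal(mod[["GKr"]], base[["GKr"]] * 0.30)
  expect_equal(mod[["GKs"]], base[["GKs"]] * 0.20)
  untouched <- setdiff(names(base), c("GNa", "GKr", "GKs"))
  expect_equal(mod[untouched], base[untouched])
})

test_that("resting cell stays at rest and a stimulus elicits an AP", {
  rest <- singleCellRun(tp06Params("epi"), duration = 1000)
  expect_lt(max(abs(rest$V - rest$V[1])), 1)
  ap <- singleCellRun(tp06Params("epi"), duration = 400, stimTimes = 10,
                      amplitude = 26)
  expect_gt(max(ap$V), 0)                  # overshoot
  expect_lt(ap$V[length(ap$V)], -80)       # back to rest
})

test_that("single-cell APD90 matches the continuous-equation oracle", {
  skip_if_not_installed("deSolve")
  for (variant in c("epi", "spiral")) {
    prm <- tp06Params(variant)
    ref <- oracleApd90(prm)
    ap <- singleCellRun(prm, duration = 450, stimTimes = 10,
                        amplitude = 26, dt = 0.02)
    expect_lt(abs(apd(ap$times, ap$V) - ref), 2,
              label = sprintf("APD90 mismatch (%s)", variant))
  }
})

test_that("time-step refinement changes the paced AP by less than 1 mV", {
  prm <- tp06Params("epi")
  a <- singleCellRun(prm, duration = 450, stimTimes = 10, amplitude = 26,
                     dt = 0.02, probeStride = 1)
  b <- singleCellRun(prm, duration = 450, stimTimes = 10, amplitude = 26,
                     dt = 0.002, probeStride = 1)
  # compare on the common 1 ms sampling, away from the upstroke sample
  d <- abs(a$V - b$V)
  expect_lt(sort(d, decreasing = TRUE)[3], 1)
})

test_that("remodeling at f = 40% prolongs the single-cell APD", {
  base <- tp06Params("epi")
  mod <- applyRemodeling(40, base)
  a0 <- singleCellRun(base, duration = 600, stimTimes = 10, amplitude = 26)
  a1 <- singleCellRun(mod, duration = 600, stimTimes = 10, amplitude = 40)
  expect_gt(apd(a1$times, a1$V), apd(a0$times, a0$V))
})

test_that("non-finite states are rejected with the variable named", {
  st <- tp06RestingState()
  st[["cai"]] <- NaN
  expect_error(tp06Derivs(st), "cai")
})

test_that("derivatives vanish nowhere but stay consistent with the oracle", {
  skip_if_not_installed("deSolve")
  st <- tp06RestingState()
  st[["V"]] <- -20; st[["m"]] <- 0.5; st[["d"]] <- 0.3
  mine <- tp06Derivs(st, tp06Params("epi"))
  ref <- oracleRhs(0, st, list(prm = tp06Params("epi")))[[1]]
  expect_equal(as.numeric(mine), as.numeric(ref), tolerance = 1e-8)
})
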