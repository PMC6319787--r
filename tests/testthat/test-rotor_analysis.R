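# Phase-singularity detection, period measurement, classification.

test_that("uniform frames contain no singularities", {
  v <- matrix(-85, 20, 20)
  expect_equal(nrow(detectPhaseSingularities(v, v)), 0)
})

test_that("an analytic spiral yields one singularity of known chirality", {
  for (chir in c(1, -1)) {
    fr <- spiralFrames(40, 40, chirality = chir)
    ps <- detectPhaseSingularities(fr$v1, fr$v0)
    expect_equal(nrow(ps), 1)
    expect_lt(abs(ps$row - 20.5), 1.5)
    expect_lt(abs(ps$col - 20.5), 1.5)
    ref <- oracleWinding(fr$v1, fr$v0)
    expect_equal(ps$charge, ref$charge)
  }
})

test_that("fast detector equals the brute-force winding oracle", {
  set.seed(31)
  for (k in 1:5) {
    v1 <- matrix(runif(30 * 25, -90, 30), 30, 25)
    v0 <- matrix(runif(30 * 25, -90, 30), 30, 25)
    obst <- matrix(runif(30 * 25) < 0.1, 30, 25)
    a <- detectPhaseSingularities(v1, v0, obst)
    b <- oracleWinding(v1, v0, obst)
    expect_equal(nrow(a), nrow(b))
    if (nrow(a)) {
      oa <- order(a$row, a$col); ob <- order(b$row, b$col)
      expect_equal(a$row[oa], b$row[ob])
      expect_equal(a$col[oa], b$col[ob])
      expect_equal(a$charge[oa], b$charge[ob])
    }
  }
})

test_that("a figure-eight pattern has two singularities of zero net charge", {
  # analytic phase field with winding +1 around P1 and -1 around P2
  nr <- 40; nc <- 48
  p1 <- c(20.5, 14.5); p2 <- c(20.5, 34.5)
  rr <- outer(seq_len(nr), rep(1, nc))
  cc <- outer(rep(1, nr), seq_len(nc))
  theta <- atan2(cc - p1[2], rr - p1[1]) - atan2(cc - p2[2], rr - p2[1])
  v1 <- -40 + 40 * sin(theta); v0 <- -40 + 40 * cos(theta)
  ps <- detectPhaseSingularities(v1, v0)
  expect_equal(nrow(ps), 2)
  expect_equal(sum(ps$charge), 0)
  ref <- oracleWinding(v1, v0)
  expect_equal(sort(ps$col), sort(ref$col))
})

test_that("plaquettes touching obstacles are skipped", {
  fr <- spiralFrames(30, 30, center = c(15.5, 15.5))
  obst <- matrix(FALSE, 30, 30); obst[15:16, 15:16] <- TRUE
  ps <- detectPhaseSingularities(fr$v1, fr$v0, obst)
  expect_equal(nrow(ps), 0)   # core plaquette masked
})

test_that("frames of mismatched shape are rejected", {
  expect_error(detectPhaseSingularities(matrix(0, 5, 5), matrix(0, 5, 4)),
               "dimension")
})

# synthetic recording with given activation times per probe
syntheticRecording <- function(pulseTimes, duration = 2000, nProbes = 4,
                               frameV = NULL, frameTimes = seq(0, duration, 10)) {
  tt <- seq(0, duration, by = 1)
  tr <- vapply(seq_len(nProbes), function(q) {
    v <- rep(-85, length(tt))
    for (p in pulseTimes) v[tt >= p & tt <= p + 100] <- 10
    v
  }, numeric(length(tt)))
  grid <- tissueGrid(matrix(0, 4, 4))
  fr <- if (is.null(frameV))
    vapply(frameTimes, function(t) rep(-85, 16), numeric(16))
  else frameV
  new("SimRecording", frames = fr, frameTimes = frameTimes,
      probes = tr, probeTimes = tt,
      probeIndex = cbind(rep(1, nProbes), seq_len(nProbes)),
      ecg = numeric(0), ecgTimes = numeric(0),
      actTime = matrix(NA_real_, 4, 4),
      finalState = matrix(rep(tp06RestingState(), each = 16), 16, 19),
      grid = grid, config = simConfig(duration = duration),
      configHash = "synthetic", stopReason = "completed",
      stopTime = NA_real_)
}

test_that("period is the median inter-activation interval in the window", {
  r300 <- syntheticRecording(seq(200, 1900, by = 300), duration = 2000)
  expect_equal(measurePeriod(r300, 2000, window = 1000), 300)
  r222 <- syntheticRecording(seq(100, 1900, by = 222), duration = 2000)
  expect_equal(measurePeriod(r222, 2000, window = 1000), 222)
})

test_that("quiescent traces give a window-censored period", {
  rq <- syntheticRecording(numeric(0), duration = 1000)
  expect_equal(measurePeriod(rq, 1000, window = 320), 320)
})

test_that("classifier truth table on synthetic recordings", {
  # all-subthreshold frames at the classification time -> terminated
  rq <- syntheticRecording(c(100, 400), duration = 2000)
  out <- classifyOutcome(rq)
  expect_equal(outcomeLabel(out), "terminated")
  # period 300 ms with active frames -> anchored
  fr <- spiralFrames(4, 4)
  frames <- vapply(seq(0, 2000, 10), function(t) as.vector(fr$v1),
                   numeric(16))
  ra <- syntheticRecording(seq(200, 1900, 300), frameV = frames)
  outA <- classifyOutcome(ra)
  expect_match(outcomeLabel(outA), "^anchored")
  expect_gt(outA@period, 280)
  # period 222 ms with active frames -> not anchored
  # phase chosen so two activations fall inside the 320 ms window
  rn <- syntheticRecording(seq(150, 2000, 222), frameV = frames)
  expect_equal(outcomeLabel(classifyOutcome(rn)), "not_anchored")
})

test_that("a too-short recording is rejected with the required duration", {
  r <- syntheticRecording(seq(100, 900, 300), duration = 1000)
  expect_error(classifyOutcome(r, classificationTime = 5000), "ms")
})

test_that("time-to-anchor finds the onset of sustained slowing", {
  activeFrames <- function(duration)
    vapply(seq(0, duration, 10), function(t) rep(0, 16), numeric(16))
  # 222 ms rhythm until 5 s, 300 ms afterwards
  pulses <- c(seq(100, 5000, 222), seq(5100, 9900, 300))
  r <- syntheticRecording(pulses, duration = 10000,
                          frameV = activeFrames(10000))
  tta <- timeToAnchor(r)
  expect_gt(tta, 4500); expect_lt(tta, 5600)
  # immediately-slow series: onset at the start (within one window)
  r0 <- syntheticRecording(seq(100, 9900, 300), duration = 10000,
                           frameV = activeFrames(10000))
  expect_lt(timeToAnchor(r0), 400)
  # transient excursion above threshold is ignored
  pul <- c(seq(100, 3000, 222), seq(3100, 4000, 310), seq(4100, 7000, 222),
           seq(7100, 9900, 300))
  rt <- timeToAnchor(syntheticRecording(pul, duration = 10000,
                                        frameV = activeFrames(10000)))
  expect_gt(rt, 6500)
})
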