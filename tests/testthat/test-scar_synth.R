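# Synthetic scar generation: fibrosis fields, seeded textures, controls.

test_that("radial-linear scar profile interpolates from center to rim", {
  spec <- scarSpec(c(65, 65), diameter = 3.2, level = 50)  # radius 64 nodes
  m <- makeFibrosisMap(spec, c(129, 129))
  pct <- fibrosisPct(m)
  expect_equal(pct[65, 65], 50)
  expect_equal(pct[65, 65 + 32], 25, tolerance = 0.5)  # half-radius
  expect_equal(pct[65, 65 + 64], 0)                    # rim
  expect_equal(pct[1, 1], 0)                           # far field
})

test_that("uniform scar profile is constant inside and zero outside", {
  spec <- scarSpec(c(65, 65), diameter = 3.2, "uniform", level = 30)
  pct <- fibrosisPct(makeFibrosisMap(spec, c(129, 129)))
  inside <- pct[65, 65 + 0:63]
  expect_true(all(inside == 30))
  expect_true(all(pct[1, ] == 0))
  expect_setequal(unique(as.vector(pct)), c(0, 30))
})

test_that("a 6.4 cm scar at 250 um spacing spans 128 nodes of radius", {
  spec <- scarSpec(c(150, 150), diameter = 6.4, level = 50)
  pct <- fibrosisPct(makeFibrosisMap(spec, c(300, 300)))
  expect_gt(pct[150, 150 + 127], 0)   # just inside the rim
  expect_equal(pct[150, 150 + 128], 0)  # at the rim
  expect_equal(pct[150 - 128, 150], 0)
})

test_that("scars that do not fit the grid are rejected", {
  expect_error(makeFibrosisMap(scarSpec(c(10, 10), 6.4), c(100, 100)),
               "fit")
})

test_that("degenerate fibrosis levels give empty and full masks", {
  expect_equal(sum(obstacleMask(sampleTexture(matrix(0, 30, 30)))), 0)
  expect_equal(sum(obstacleMask(sampleTexture(matrix(100, 30, 30)))), 900)
})

test_that("texture obstacle fraction lies in the binomial band", {
  # f = 30% over 10^4 nodes: 99.9% band from qbinom
  tex <- sampleTexture(matrix(30, 100, 100), seed = 7)
  frac <- mean(obstacleMask(tex))
  band <- qbinom(c(5e-4, 1 - 5e-4), 1e4, 0.3) / 1e4
  expect_gte(frac, band[1])
  expect_lte(frac, band[2])
})

test_that("textures are reproducible and monotone in fibrosis level", {
  map <- matrix(25, 50, 50)
  t1 <- sampleTexture(map, seed = 11)
  t2 <- sampleTexture(map, seed = 11)
  expect_identical(obstacleMask(t1), obstacleMask(t2))
  t3 <- sampleTexture(map, seed = 12)
  expect_false(identical(obstacleMask(t1), obstacleMask(t3)))
  # shared uniform field: raising f pointwise only adds obstacles
  hi <- sampleTexture(matrix(40, 50, 50), seed = 11)
  expect_true(all(obstacleMask(hi)[obstacleMask(t1)]))
})

test_that("texture sampling leaves the global RNG stream untouched", {
  set.seed(99); before <- .Random.seed
  sampleTexture(matrix(50, 20, 20), seed = 3)
  expect_identical(.Random.seed, before)
})

test_that("controls: no_scar empty, necrotic_only a solid binary disk", {
  spec <- scarSpec(c(64, 64), diameter = 3.2, level = 50)
  ctl <- makeControls(spec, c(128, 128))
  expect_equal(sum(obstacleMask(ctl$no_scar)), 0)
  mask <- obstacleMask(ctl$necrotic_only)
  # count = nodes strictly inside the disk radius
  rr <- (row(mask) - 64) * 0.025; cc <- (col(mask) - 64) * 0.025
  expect_equal(sum(mask), sum(sqrt(rr^2 + cc^2) < 1.6))
  # no partial fibrosis anywhere in either control
  expect_true(all(fibrosisPct(ctl$necrotic_only) == 0))
  expect_true(all(fibrosisPct(ctl$no_scar) == 0))
})
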