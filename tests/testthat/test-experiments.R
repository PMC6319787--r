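# Experiment drivers: error capture, tidy outputs, aggregation.

test_that("failed runs are recorded as 'failed', never dropped", {
  # a domain too small for the requested distance fails at initiation
  tab <- runDistanceSweep(distances = 8, seeds = 1:2, dims = c(48, 64),
                          duration = 400, diameter = 1,
                          classificationTime = 400)
  expect_equal(nrow(tab), 2)
  expect_true(all(tab$label == "failed"))
  fr <- attr(tab, "fractions")
  expect_equal(fr$fraction[fr$label == "failed"], 1)
})

test_that("phase-diagram labeling applies the 65% anchored-fraction rule", {
  # drive the labeling logic through an impossible geometry: all runs
  # fail, the anchored fraction is 0 and the cell reads No Attraction
  pd <- runPhaseDiagram(diameters = 1, levels = 30, distance = 4,
                        seeds = 1:2, dims = c(48, 64), duration = 400)
  expect_equal(pd$label, "No Attraction")
  expect_equal(pd$fraction_anchored, 0)
})

test_that("outcome records round-trip to one-row data frames", {
  rec <- new("OutcomeRecord", label = "anchored_single_ccw", period = 305,
             classificationTime = 20000, timeToAnchor = 5200, nArms = 1L,
             seed = 7L, configHash = "abc")
  df <- as.data.frame(rec)
  expect_equal(nrow(df), 1)
  expect_equal(df$label, "anchored_single_ccw")
  expect_equal(df$time_to_anchor, 5200)
  expect_error(new("OutcomeRecord", label = "bogus", period = 1,
                   classificationTime = 1, timeToAnchor = 1, nArms = 0L,
                   seed = 1L, configHash = "x"), "label")
})
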