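cmpTimes <- seq(0, 20000, by = 20)

test_that("one-sided inhibitor doses select the expected pathway", {
  # inhibitor only on the AB circuit: B delayed, C divides first (Pathway 1)
  p1 <- runComparatorCondition(1.25, 0, handicap = 1, KAB = 0.1, KAC = 0.1,
                               times = cmpTimes)
  expect_equal(p1@pathway, "Pathway 1")
  expect_gt(p1@deltaTau, 0)
  # inhibitor only on the AC circuit: mirror image (Pathway 2)
  p2 <- runComparatorCondition(0, 1.25, handicap = 1, KAB = 0.1, KAC = 0.1,
                               times = cmpTimes)
  expect_equal(p2@pathway, "Pathway 2")
  expect_equal(p2@deltaTau, -p1@deltaTau, tolerance = 1e-6)
})

test_that("fully symmetric conditions give a vanishing time difference", {
  res <- runComparatorCondition(0.75, 0.75, handicap = 1, KAB = 0.1,
                                KAC = 0.1, times = cmpTimes)
  expect_lt(abs(res@deltaTau), 1e-6)
})

test_that("delta tau responds monotonically to each input dose", {
  dAB <- sapply(c(0.5, 0.9, 1.25), function(cab)
    runComparatorCondition(cab, 0.75, times = cmpTimes)@deltaTau)
  expect_true(all(diff(dAB) > 0))     # more AB inhibitor delays B
  dAC <- sapply(c(0.5, 0.9, 1.25), function(cac)
    runComparatorCondition(0.75, cac, times = cmpTimes)@deltaTau)
  expect_true(all(diff(dAC) < 0))     # more AC inhibitor delays C
})

test_that("shared-enzyme competition delays the whole reaction with total dose", {
  eff <- totalDoseEffect(c(1.0, 2.0), deltaC = 0.5, times = cmpTimes)
  expect_true(eff$tauBMonotone)
  expect_true(eff$tauCMonotone)
  expect_gt(eff$table$tauB[2], eff$table$tauB[1])
  expect_gt(eff$table$tauC[2], eff$table$tauC[1])
  # with enzyme in vast excess the competition effect disappears
  rich <- totalDoseEffect(c(1.0, 2.0), deltaC = 0.5, enzyme = 500,
                          times = seq(0, 2000, by = 2))
  expect_lt(abs(rich$table$tauB[2] / rich$table$tauB[1] - 1), 0.01)
  # independent-enzyme mode refuses: the result would be vacuous
  expect_error(totalDoseEffect(c(1, 2), competition = "independent"),
               "shared")
})

test_that("in independent mode one circuit ignores the other's dose", {
  tauBAt <- function(cac)
    runComparatorCondition(0.75, cac, competition = "independent",
                           times = cmpTimes)@tauB
  expect_equal(tauBAt(0), tauBAt(1.25), tolerance = 1e-4)
  # whereas under the shared pool the other dose matters
  tauBShared <- function(cac)
    runComparatorCondition(0.75, cac, times = cmpTimes)@tauB
  expect_gt(tauBShared(1.25) / tauBShared(0), 1.05)
})

test_that("a stronger rate handicap pushes the offset further negative", {
  # the bracket-midpoint sigma is quantized to the dose grid, so the ordering
  # is asserted on the bisection-refined estimate
  weak <- runComparatorSweep(handicap = 2, refine = TRUE, refineIter = 4,
                             times = cmpTimes)
  strong <- runComparatorSweep(refine = TRUE, refineIter = 4,
                               times = cmpTimes)
  expect_equal(strong@sigma, -0.75)
  expect_gt(weak@sigmaRefined, strong@sigmaRefined)
})

test_that("well-mixed and high-diffusion spatial engines agree on pathways", {
  # matched initial conditions (uniform layout): the spatial engine at high
  # diffusion must reproduce the well-mixed pathway call on every condition
  g <- gridSpec(16, 16, spacing = 10, radius = 40)
  dm <- uniformDmap(20)
  conds <- comparatorPresetConditions()
  tRD <- seq(0, 24000, by = 400)
  for (i in seq_len(nrow(conds))) {
    wmRes <- runComparatorCondition(conds$cTildeAB[i], conds$cTildeAC[i],
                                    times = cmpTimes)
    rdRes <- runComparatorCondition(conds$cTildeAB[i], conds$cTildeAC[i],
                                    engine = "reaction-diffusion",
                                    times = tRD, grid = g, dmap = dm,
                                    rdLayout = "uniform")
    expect_equal(rdRes@pathway, wmRes@pathway,
                 info = sprintf("condition %d", i))
  }
})

test_that("sweeps assemble the table, offset and refusals correctly", {
  sw <- runComparatorSweep(comparatorPresetConditions()[3:4, ],
                           times = cmpTimes)
  expect_equal(nrow(sw@table), 2)
  expect_identical(sw@sigmaStatus, "ok")
  expect_equal(sw@sigma, -0.75)
  # two conditions on the same side of the switch: no sign change
  swNo <- runComparatorSweep(comparatorPresetConditions()[1:2, ],
                             times = cmpTimes)
  expect_identical(swNo@sigmaStatus, "outside range")
  expect_true(is.na(swNo@sigma))
})
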