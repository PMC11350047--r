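test_that("Michaelis-Menten release rate obeys its identities", {
  expect_equal(mmReleaseRate(0, kCat = 2e-3, Km = 0.5, cE = 0.25), 0)
  # half-saturation: u = Km gives half the maximal rate
  expect_equal(mmReleaseRate(0.5, kCat = 2e-3, Km = 0.5, cE = 0.25),
               2e-3 * 0.25 / 2)
  # saturation limit
  expect_equal(mmReleaseRate(1e6, kCat = 2e-3, Km = 0.5, cE = 0.25),
               2e-3 * 0.25, tolerance = 1e-5)
  # shared-enzyme competition lowers the rate via the summed denominator
  expect_lt(mmReleaseRate(0.5, 2e-3, 0.5, 0.25, uITTotal = 2.0),
            mmReleaseRate(0.5, 2e-3, 0.5, 0.25))
  expect_error(mmReleaseRate(-1, 2e-3, 0.5, 0.25), "non-negative")
})

test_that("inhibition rate is bilinear mass action", {
  expect_equal(inhibitionRate(1, 0, 0.05), 0)
  expect_equal(inhibitionRate(1.0, 2.0, 1e-3), 2e-3)
  # doubling both concentrations quadruples the rate
  expect_equal(inhibitionRate(2, 4, 0.05), 4 * inhibitionRate(1, 2, 0.05))
  expect_error(inhibitionRate(-0.1, 1, 0.05), "non-negative")
})

test_that("time-delay net rate equals release minus inhibition", {
  m <- fastDelayedModel(cTilde = 1.5)
  state <- initialState(m)
  state["T.AB.1"] <- 0.2; state["R.AB.1"] <- 0.3
  g <- gTD(state, m)
  # independently recomposed from the elementary rate laws
  relHand <- m@kCat * m@enzyme * state[["iT.AB.1"]] /
    (m@Km + state[["iT.AB.1"]])
  inhHand <- m@kHybRNA * state[["T.AB.1"]] * state[["R.AB.1"]]
  expect_equal(unname(g["T.AB.1"]), relHand - inhHand)
  # no substrate and no inhibitor: zero net rate
  z <- state; z["iT.AB.2"] <- 0; z["R.AB.2"] <- 0
  expect_equal(unname(gTD(z, m)["T.AB.2"]), 0)
  # a balanced state: choose T so inhibition equals release
  b <- state
  b["T.AB.1"] <- relHand / (m@kHybRNA * b[["R.AB.1"]])
  expect_equal(unname(gTD(b, m)["T.AB.1"]), 0, tolerance = 1e-12)
})

test_that("strand-displacement rates vanish without triggers and assemble the rhs", {
  m <- fastDelayedModel()
  state <- initialState(m)
  state[grep("^T\\.", names(state))] <- 0
  f <- fHSD(state, m)
  expect_true(all(f$triggerConsumption == 0))
  expect_true(all(f$siteRates == 0))
  # rhs assembles gTD, fHSD and linker bookkeeping
  st <- initialState(m)
  st["T.AB.1"] <- 0.2
  rhs <- rhsWellMixed(st, m)
  g <- gTD(st, m); f <- fHSD(st, m)
  expect_equal(unname(rhs["T.AB.1"]),
               unname(g["T.AB.1"] - f$triggerConsumption["T.AB.1"]))
  expect_equal(unname(rhs["Sf.AB.1"]), unname(f$siteRates["Sf.AB.1"]))
  # all-zero state has zero derivative
  zero <- st * 0
  expect_true(all(rhsWellMixed(zero, m) == 0))
  expect_error(rhsWellMixed(st[-1], m), "missing species")
})

test_that("well-mixed trajectories respect the conservation laws", {
  for (cT in c(0, 0.75, 1.5)) {
    m <- fastDelayedModel(cTilde = cT)
    traj <- simulateWellMixed(m, seq(0, 1500, by = 25), rtol = 1e-8,
                              atol = 1e-10)
    expect_true(all(traj@states >= 0))
    # trigger strand conservation: free + inhibited + linker-bound constant
    tot <- triggerTotals(traj, "AB")
    expect_lt(max(abs(tot / tot[1, ][col(tot)] - 1)), 1e-6)
    # inhibitor RNA total non-increasing under active enzyme
    rTot <- inhibitorTotals(traj, "AB")
    expect_true(all(diff(rTot[, 1]) <= 1e-9))
    # intact linker non-increasing, uncleaved fraction non-increasing
    intact <- (traj@states[, "Sf.AB.1"] / 0.6) * (traj@states[, "Sf.AB.2"] / 0.6)
    expect_true(all(diff(intact) <= 1e-9))
    expect_true(all(diff(uncleavedFraction(traj, "AB")) <= 1e-9))
  }
})

test_that("no enzyme plus excess inhibitor freezes the circuit", {
  m <- fastDelayedModel(cTilde = 2, enzyme = 0)
  # start with some free trigger despite the excess inhibitor
  init <- initialState(m)
  init["T.AB.1"] <- init["T.AB.2"] <- 0.3
  traj <- simulateWellMixed(m, seq(0, 4000, by = 50), init = init)
  # free trigger decays towards zero (sequestered by the inhibitor excess)
  expect_lt(speciesTrace(traj, "T.AB.1")[81], 1e-3)
  # cleavage stalls at a partial level
  w <- uncleavedFraction(traj, "AB")
  expect_gt(w[81], 0.2)
  expect_lt(abs(w[81] - w[61]), 1e-3)
})

test_that("without inhibitor the delayed circuit matches a plain circuit", {
  mDel <- fastDelayedModel(cTilde = 0)
  mPlain <- circuitModel(linkerCircuit("AB", 0.6, 1, delayed = FALSE),
                         enzyme = 2, kCat = 2e-3)
  tt <- seq(0, 600, by = 10)
  wDel <- uncleavedFraction(simulateWellMixed(mDel, tt), "AB")
  wPlain <- uncleavedFraction(simulateWellMixed(mPlain, tt), "AB")
  expect_equal(wDel, wPlain, tolerance = 1e-6)
})

test_that("crossing times order with enzyme and inhibitor dose", {
  tt <- seq(0, 4000, by = 20)
  tCross <- function(enzyme, cTilde) {
    m <- fastDelayedModel(cTilde = cTilde, enzyme = enzyme)
    w <- uncleavedFraction(simulateWellMixed(m, tt), "AB")
    as.numeric(divisionTime(divisionTraceFromRatios(tt, 1 - w), level = 0.5))
  }
  # more enzyme: earlier crossing; more inhibitor: later crossing
  byEnzyme <- sapply(c(0.5, 1, 2), function(e) tCross(e, 1.5))
  expect_true(all(diff(byEnzyme) < 0))
  byDose <- sapply(c(1.0, 1.5, 2.0), function(ct) tCross(2, ct))
  expect_true(all(diff(byDose) > 0))
})

test_that("fast displacement collapses the two-step scheme onto single-step", {
  tt <- seq(0, 600, by = 10)
  m2 <- circuitModel(linkerCircuit("AB", 0.6, 1, kOn = 0.1, kDisp = 1000),
                     enzyme = 0, sdMode = "two-step")
  m1 <- circuitModel(linkerCircuit("AB", 0.6, 1, kOn = 0.1),
                     enzyme = 0, sdMode = "single-step")
  w2 <- uncleavedFraction(simulateWellMixed(m2, tt, rtol = 1e-8), "AB")
  w1 <- uncleavedFraction(simulateWellMixed(m1, tt, rtol = 1e-8), "AB")
  expect_lt(max(abs(w2 - w1)), 5e-3)
  # and the agreement tightens as the displacement step gets faster
  m2slow <- circuitModel(linkerCircuit("AB", 0.6, 1, kOn = 0.1, kDisp = 10),
                         enzyme = 0, sdMode = "two-step")
  wSlow <- uncleavedFraction(simulateWellMixed(m2slow, tt, rtol = 1e-8), "AB")
  expect_gt(max(abs(wSlow - w1)), max(abs(w2 - w1)))
})

test_that("saturating trigger excess gives pseudo-first-order linker decay", {
  # single-step mode, huge trigger excess: sites decay exp(-kOn * T * t)
  m <- circuitModel(linkerCircuit("AB", 0.01, 50, kOn = 0.01),
                    enzyme = 0, sdMode = "single-step")
  tt <- seq(0, 10, by = 0.5)
  traj <- simulateWellMixed(m, tt, rtol = 1e-10, atol = 1e-12)
  sf <- speciesTrace(traj, "Sf.AB.1")
  expect_equal(sf, 0.01 * exp(-0.01 * 50 * tt), tolerance = 1e-3)
})

test_that("integration rejects bad inputs", {
  m <- fastDelayedModel()
  expect_error(simulateWellMixed(m, c(0, 0, 1)), "strictly increasing")
  bad <- initialState(m); bad[1] <- -1
  expect_error(simulateWellMixed(m, c(0, 1), init = bad), "non-negative")
})
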