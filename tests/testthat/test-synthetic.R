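test_that("circle-overlap ground truth matches its geometry", {
  r <- 10
  expect_equal(circleOverlapArea(0, r), pi * r^2)
  expect_equal(circleOverlapArea(2 * r, r), 0)
  expect_equal(circleOverlapArea(25, r), 0)     # beyond contact
  # numeric quadrature oracle for an intermediate separation
  d <- 8
  integrand <- function(x) {
    # width of the lens at horizontal position x (circles at 0 and d)
    h1 <- sqrt(pmax(r^2 - x^2, 0))
    h2 <- sqrt(pmax(r^2 - (x - d)^2, 0))
    2 * pmin(h1, h2)
  }
  quad <- stats::integrate(integrand, d / 2 - r, d / 2 + r)$value
  expect_equal(circleOverlapArea(d, r), quad, tolerance = 1e-6)
  # schedule endpoints
  expect_equal(scheduleDivisionRatio(c(0, 2 * r), r), c(0, 1))
})

test_that("movie generation is deterministic and guards its preconditions", {
  a <- makeDivisionMovie(nFrames = 6, readNoise = 0.02, shotScale = 200,
                         seed = 3)
  b <- makeDivisionMovie(nFrames = 6, readNoise = 0.02, shotScale = 200,
                         seed = 3)
  expect_identical(a$stack@data, b$stack@data)
  expect_error(makeDivisionMovie(nFrames = 6, readNoise = 0.02), "seed")
  expect_error(makeDivisionMovie(nFrames = 4, frameDim = c(50, 50),
                                 radius = 20,
                                 separation = c(0, 10, 30, 60)),
               "leave the frame")
  expect_error(makeDivisionMovie(nFrames = 5, separation = c(0, 1)),
               "every frame")
  # zero separation throughout: ground truth identically zero
  still <- makeDivisionMovie(nFrames = 4, separation = rep(0, 4))
  expect_equal(still$truth$rDiv, rep(0, 4))
  # final separation beyond 2 r: ground truth reaches exactly one
  full <- makeDivisionMovie(nFrames = 4,
                            separation = c(0, 10, 30, 45), radius = 20,
                            frameDim = c(120, 120))
  expect_equal(full$truth$rDiv[4], 1)
})

test_that("the image pipeline recovers the analytic schedule", {
  mv <- makeDivisionMovie(nFrames = 30)
  r <- divisionTraceFromStack(mv$stack)$B@rDiv
  expect_lt(max(abs(r - mv$truth$rDiv)), 0.02)
  # seeded noise moves the division time by less than one frame
  mvN <- makeDivisionMovie(nFrames = 30, readNoise = 0.02, shotScale = 200,
                           bgDrift = 0.1, seed = 7)
  rN <- divisionTraceFromStack(mvN$stack)$B@rDiv
  t0 <- as.numeric(divisionTime(divisionTraceFromRatios(1:30, r)))
  tN <- as.numeric(divisionTime(divisionTraceFromRatios(1:30, rN)))
  expect_lt(abs(tN - t0), 1)
  # and the extracted time matches the generator's analytic midpoint
  tTruth <- as.numeric(divisionTime(
    divisionTraceFromRatios(1:30, mv$truth$rDiv)))
  expect_lt(abs(t0 - tTruth), 1)
})

test_that("ternary movies reproduce programmed pathways and delta tau", {
  byOrder <- list(
    p1 = list(sepCStart = 0.15, sepBStart = 0.60, expect = "Pathway 1"),
    p2 = list(sepCStart = 0.60, sepBStart = 0.15, expect = "Pathway 2")
  )
  for (cs in byOrder) {
    n <- 60
    tm <- makeTernaryMovie(
      nFrames = n,
      sepB = separationSchedule(n, round(cs$sepBStart * n),
                                round(cs$sepBStart * n) + 18, 48),
      sepC = separationSchedule(n, round(cs$sepCStart * n),
                                round(cs$sepCStart * n) + 18, 48))
    tr <- divisionTraceFromStack(tm$stack)
    est <- deltaTau(divisionTime(tr$B), divisionTime(tr$C))
    expect_equal(est$pathway, cs$expect)
    expect_equal(tm$tauTruth$pathway, cs$expect)
    expect_lt(abs(est$deltaTau - tm$tauTruth$deltaTau), 1)
  }
  # simultaneous separation: |delta tau| within one frame
  n <- 40
  sep <- separationSchedule(n, 10, 30, 48)
  tmEq <- makeTernaryMovie(nFrames = n, sepB = sep, sepC = sep)
  trEq <- divisionTraceFromStack(tmEq$stack)
  dEq <- deltaTau(divisionTime(trEq$B), divisionTime(trEq$C))
  expect_lt(abs(dEq$deltaTau), 1)
})

test_that("noisy trace generation reduces to the simulator at sigma 0", {
  m <- fastDelayedModel()
  tt <- seq(0, 500, by = 50)
  o0 <- makeNoisyTraces(m, tt, sigma = 0)
  expect_equal(o0$w, o0$wTrue)
  expect_error(makeNoisyTraces(m, tt, sigma = 0.05), "seed")
  o1 <- makeNoisyTraces(m, tt, sigma = 0.05, seed = 4)
  o2 <- makeNoisyTraces(m, tt, sigma = 0.05, seed = 4)
  expect_identical(o1, o2)
  expect_true(all(o1$w >= 0))
})
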