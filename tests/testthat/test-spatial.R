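test_that("the no-flux Laplacian matches a brute-force stencil", {
  # uniform field: identically zero
  expect_true(all(laplacianNoFlux(matrix(3, 6, 6), 1) == 0))
  # single spike: 4-neighbour pattern summing to zero
  f <- matrix(0, 5, 5); f[3, 3] <- 1
  lap <- laplacianNoFlux(f, 2)
  expect_equal(lap[3, 3], -4 / 4)
  expect_equal(lap[2, 3], 1 / 4)
  expect_equal(sum(lap), 0)
  # random field: cell-by-cell brute-force loop with reflecting boundaries
  set.seed(9)
  f <- matrix(runif(48), 6, 8); h <- 0.7
  ref <- f * 0
  for (i in 1:6) for (j in 1:8) {
    up <- f[max(i - 1, 1), j]; dn <- f[min(i + 1, 6), j]
    lf <- f[i, max(j - 1, 1)]; rt <- f[i, min(j + 1, 8)]
    ref[i, j] <- (up + dn + lf + rt - 4 * f[i, j]) / h^2
  }
  expect_equal(laplacianNoFlux(f, h), ref)
  expect_equal(sum(laplacianNoFlux(f, h)), 0, tolerance = 1e-12)
  expect_error(laplacianNoFlux(1:5, 1), "matrix")
})

test_that("pure diffusion conserves mass to round-off", {
  m <- circuitModel(linkerCircuit("X", 0.5, 0), enzyme = 0)
  g <- smallGrid()
  set.seed(1)
  fl <- initialFields(m, g, layout = "uniform")
  fl[["Sf.X.1"]] <- matrix(runif(64), 8, 8)
  rd <- simulateRD(m, g, uniformDmap(5), seq(0, 50, by = 10), init = fl)
  drift <- abs(rd@domainMeans[, "Sf.X.1"] / mean(fl[["Sf.X.1"]]) - 1)
  expect_lt(max(drift), 1e-10)
})

test_that("the compiled stepper agrees with the R reference stepper", {
  cfg <- spatialDropletConfig(nx = 16, ny = 16, spacing = 10)
  fl <- initialFields(cfg$model, cfg$grid)
  h <- 0.2 * 10^2 / (4 * 10)
  ref <- stepRD(fl, h, cfg$grid, cfg$dmap, cfg$model)$fields
  traj <- simulateRD(cfg$model, cfg$grid, cfg$dmap, times = c(0, h), dt = h)
  for (nm in speciesNames(cfg$model)) {
    expect_equal(unname(traj@domainMeans[2, nm]), mean(ref[[nm]]),
                 tolerance = 1e-12)
  }
})

test_that("explicit stepping rejects unstable steps", {
  cfg <- spatialDropletConfig(nx = 16, ny = 16, spacing = 10)
  fl <- initialFields(cfg$model, cfg$grid)
  bound <- cfg$grid@spacing^2 / (4 * 10)
  expect_error(stepRD(fl, 2 * bound, cfg$grid, cfg$dmap, cfg$model),
               "stability")
  expect_error(simulateRD(cfg$model, cfg$grid, cfg$dmap, c(0, 1),
                          dt = 2 * bound), "stability")
})

test_that("reaction-only spatial dynamics match the per-cell ODE", {
  m <- fastDelayedModel()
  g <- smallGrid()
  t2 <- seq(0, 300, by = 100)
  rd <- simulateRD(m, g, uniformDmap(0), t2, dt = 0.02, layout = "uniform")
  ode <- simulateWellMixed(m, t2, rtol = 1e-10, atol = 1e-12)
  expect_lt(max(abs(rd@domainMeans - ode@states)), 1e-6)
  # droplet layout with D = 0: nothing can enter the droplet, linkers static
  rd2 <- simulateRD(m, g, uniformDmap(0), t2, dt = 0.02)
  expect_equal(unname(rd2@dropletMeans[, "Sf.AB.1"]), rep(0.6, 4))
})

test_that("high diffusion reproduces the well-mixed kinetics", {
  m <- fastDelayedModel()
  g <- gridSpec(16, 16, spacing = 2.5, radius = 12)
  times <- seq(0, 800, by = 50)
  rd <- simulateRD(m, g, uniformDmap(20), times)
  init <- sapply(initialFields(m, g), mean)  # domain-average initial state
  wm <- simulateWellMixed(m, times, init = init)
  wRD <- uncleavedFraction(rd, "AB", region = "domain")
  wWM <- uncleavedFraction(wm, "AB")
  sel <- times >= 100                        # after the brief mixing transient
  expect_lt(max(abs(wRD[sel] - wWM[sel]) / wWM[sel]), 0.01)
})

test_that("radial profiles recover analytic fields", {
  g <- gridSpec(32, 32, spacing = 2, radius = 25)
  # uniform field: flat profile at the constant
  pr <- radialProfile(matrix(2.5, 32, 32), g, nBins = 5)
  expect_equal(pr$mean, rep(2.5, 5))
  # annulus-count-weighted mean equals the droplet mean
  set.seed(3)
  f <- matrix(runif(1024), 32, 32)
  pr <- radialProfile(f, g, nBins = 6)
  expect_equal(sum(pr$mean * pr$n) / sum(pr$n), mean(f[dropletMask(g)]))
  # radially linear field: recovered slope within discretization error
  r <- cellCoordinates(g)$r
  pr <- radialProfile(1 + 0.1 * r, g, nBins = 5)
  slope <- stats::coef(stats::lm(pr$mean ~ pr$rMid))[2]
  expect_equal(unname(slope), 0.1, tolerance = 0.05)
  # empty annuli are NA, not zero
  gTiny <- gridSpec(9, 9, spacing = 1, radius = 3)
  prT <- radialProfile(matrix(1, 9, 9), gTiny, nBins = 12)
  expect_true(anyNA(prT$mean))
  expect_error(radialProfile(matrix(1, 3, 3), g), "shape")
})
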