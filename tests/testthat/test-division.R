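test_that("Hill switch matches its identities and a 50-digit evaluation", {
  expect_equal(hillH(0, K = 0.05, n = 16), 1)
  expect_equal(hillH(0.05, K = 0.05, n = 16), 0.5)
  expect_true(all(diff(hillH(seq(0, 0.2, by = 0.01), 0.05, 16)) < 0))
  # frozen 50-digit-precision references (mpmath, dps = 50) near w = K,
  # where w^16 under/overflow would bite a naive evaluation
  ref <- c("0.04" = 0.9726230937342894684,
           "0.049" = 0.5801144693800178557,
           "0.0505" = 0.4602825321589774893,
           "0.06" = 0.05131250751958342974,
           "0.1" = 1.525855623540900560e-5,
           "1" = 1.525878906250000000e-21)
  for (w in names(ref))
    expect_equal(hillH(as.numeric(w), 0.05, 16), unname(ref[w]),
                 tolerance = 1e-12)
  expect_error(hillH(-0.1, 0.05, 16), "non-negative")
  expect_error(hillH(0.1, -1, 16), "positive")
})

test_that("division ratio normalizes to its endpoints", {
  # constant trace: never divides
  expect_equal(divisionRatio(rep(1, 5), 0.05, 16), rep(0, 5))
  # trace reaching zero uncleaved linker: fully divided
  r <- divisionRatio(c(1, 0.5, 0.05, 0), 0.05, 16)
  expect_equal(r[1], 0)
  expect_equal(r[4], 1)
  # closed form at w = K with w0 = 1 (H(1) is negligible at n = 16)
  r2 <- divisionRatio(c(1, 0.05), 0.05, 16)
  h1 <- 0.05^16 / (0.05^16 + 1)
  expect_equal(r2[2], (0.5 - h1) / (1 - h1))
  expect_error(divisionRatio(c(0, 0), 0.05, 16), "w0")
  expect_error(divisionRatio(c(0.5, 1), 0.05, 16), "maximum")
})

test_that("division ratio is monotone and bounded for monotone traces", {
  set.seed(42)
  for (rep in 1:20) {
    w <- sort(runif(30, 0, 1), decreasing = TRUE)
    w <- c(1, w)           # starts at its maximum
    K <- runif(1, 0.02, 0.9); n <- sample(2:20, 1)
    r <- divisionRatio(w, K, n)
    expect_true(all(r >= 0 & r <= 1))
    expect_true(all(diff(r) >= -1e-12))
  }
})

test_that("division times interpolate the first upward crossing", {
  # exact sample hit
  expect_equal(as.numeric(divisionTime(
    divisionTraceFromRatios(c(0, 10, 20), c(0, 0.5, 1)))), 10)
  # hand-computed linear interpolation between (10, 0.4) and (20, 0.6)
  expect_equal(as.numeric(divisionTime(
    divisionTraceFromRatios(c(0, 10, 20), c(0, 0.4, 0.6)))), 15)
  # later re-crossings are ignored: first crossing wins
  tr <- divisionTraceFromRatios(0:5, c(0, 0.6, 0.4, 0.7, 0.3, 0.9))
  expect_equal(as.numeric(divisionTime(tr)), 0.5 / 0.6)
  # capped trace reports the undivided outcome, not a number
  und <- divisionTime(divisionTraceFromRatios(0:3, c(0, 0.1, 0.2, 0.3)))
  expect_true(is.na(und))
  expect_identical(attr(und, "status"), "undivided")
})

test_that("a larger threshold K divides earlier on the same trace", {
  tt <- seq(0, 100, by = 1)
  w <- exp(-tt / 20)
  taus <- sapply(c(0.1, 0.3, 0.6, 0.9), function(K)
    as.numeric(divisionTime(divisionTrace(tt, w, K, 16))))
  expect_true(all(diff(taus) < 0))
})

test_that("delta tau maps onto pathway labels", {
  expect_equal(deltaTau(60, 10), list(deltaTau = 50, pathway = "Pathway 1"))
  expect_equal(deltaTau(30, 50), list(deltaTau = -20, pathway = "Pathway 2"))
  expect_equal(deltaTau(25, 25)$pathway, "tie")
  und <- deltaTau(NA_real_, 25)
  expect_equal(und$pathway, "undefined")
  expect_match(und$reason, "B")
})

test_that("offset estimator brackets the sign change", {
  # the printed five-condition grid and its sign pattern
  est <- estimateOffset(c(1.25, 0.5, -0.5, -1.0, -1.25),
                        c(30, 18, 7, -4, -11))
  expect_equal(est$sigma, -0.75)
  expect_equal(est$status, "ok")
  expect_equal(sort(est$bracket), c(-1.0, -0.5))
  # symmetric flip around zero
  expect_equal(estimateOffset(c(0.5, -0.5), c(10, -10))$sigma, 0)
  # ascending order is accepted too
  expect_equal(estimateOffset(c(-1.25, -1.0, -0.5, 0.5, 1.25),
                              c(-11, -4, 7, 18, 30))$sigma, -0.75)
  # no sign change: outside the tested range
  none <- estimateOffset(c(1, 0.5, 0), c(5, 4, 3))
  expect_true(is.na(none$sigma))
  expect_equal(none$status, "outside range")
  # multiple sign changes are an error listing the brackets
  expect_error(estimateOffset(c(1, 0.5, 0, -0.5), c(5, -1, 2, -3)),
               "multiple sign changes")
  expect_error(estimateOffset(c(1, -1, 0), c(1, -1, 1)), "sorted")
})
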