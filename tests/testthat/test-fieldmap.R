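# WASSR B0 estimation, spectrum recentring, and AFI B1 inversion.

wassrStack <- function(shift, gridSize = 8, noiseSd = 0) {
  ph <- fixturePhantom(gridSize = gridSize, noiseSd = noiseSd,
                       b0 = list(mode = "constant", value = shift))
  dyn <- simulateWassr(ph, wassrSchedule(), seed = 5)
  driftCorrectNormalize(dyn, wassrSchedule())
}

test_that("WASSR estimator recovers symmetric and shifted spectra", {
  zs0 <- wassrStack(0)
  b00 <- fitWassrB0(zs0)
  v0 <- b0Shift(b00)[mapMask(b00) & !b00@flat]
  expect_lt(max(abs(v0)), 1e-6)

  zs <- wassrStack(0.10)
  b0 <- fitWassrB0(zs)
  v <- b0Shift(b0)[mapMask(b0) & !b0@flat]
  expect_lt(max(abs(v - 0.10)), 0.005)
})

test_that("WASSR estimator is unbiased over shifts within +/-0.3 ppm", {
  for (s in c(-0.3, -0.15, 0.07, 0.22, 0.3)) {
    zs <- wassrStack(s)
    b0 <- fitWassrB0(zs)
    v <- b0Shift(b0)[mapMask(b0) & !b0@flat]
    expect_lt(max(abs(v - s)), 0.005)
  }
})

test_that("coarse-to-fine search matches an exhaustive grid oracle", {
  zs <- wassrStack(0.13)
  vox <- which(as.vector(zMask(zs)))[1:5]
  off <- zOffsets(zs)
  b0 <- fitWassrB0(zs)
  lagMax <- max(off) - 0.5
  lags <- seq(0.05, lagMax, by = 0.05)
  grid <- seq(-0.5, 0.5, by = 5e-4)
  for (i in vox) {
    f <- splinefun(off, zValues(zs)[i, ], method = "fmm")
    cost <- vapply(grid, function(d) mean((f(d + lags) - f(d - lags))^2),
                   numeric(1))
    oracle <- grid[which.min(cost)]
    expect_lt(abs(b0Shift(b0)[i] - oracle), 1e-3)
  }
})

test_that("flat spectra are flagged with zero shift", {
  off <- scheduleOffsets(wassrSchedule())
  flat <- stackFromValues(matrix(1, 1, length(off)), off)
  b0 <- fitWassrB0(flat)
  expect_true(b0@flat[1, 1])
  expect_identical(b0Shift(b0)[1, 1], 0)
})

test_that("recentring with a zero map is the identity, bitwise", {
  ph <- fixturePhantom()
  dyn <- simulateCestDynamics(ph, canonicalSchedule())
  zs <- driftCorrectNormalize(dyn, canonicalSchedule())
  zero <- new("B0Map", shift = matrix(0, 16, 16),
              fitQuality = matrix(0, 16, 16), mask = zMask(zs),
              flat = matrix(FALSE, 16, 16))
  out <- recenterSpectra(zs, zero)
  expect_identical(zValues(out), zValues(zs))
})

test_that("recentring undoes a simulated B0 shift away from the edges", {
  phS <- fixturePhantom(b0 = list(mode = "constant", value = 0.1))
  ph0 <- fixturePhantom(b0 = list(mode = "constant", value = 0))
  sched <- canonicalSchedule()
  zsS <- driftCorrectNormalize(simulateCestDynamics(phS, sched), sched)
  zs0 <- driftCorrectNormalize(simulateCestDynamics(ph0, sched), sched)
  shift <- matrix(0.1, 16, 16)
  rec <- recenterSpectra(zsS, new("B0Map", shift = shift,
                                  fitQuality = shift * 0, mask = zMask(zsS),
                                  flat = shift == 1))
  keep <- abs(zOffsets(rec)) <= 4.5
  m <- as.vector(zMask(rec) & zMask(zs0))
  err <- abs(zValues(rec)[m, keep] - zValues(zs0)[m, keep])
  expect_lt(max(err, na.rm = TRUE), 0.005)
})

test_that("recentring by s then -s returns the interior to tolerance", {
  ph <- fixturePhantom()
  sched <- canonicalSchedule()
  zs <- driftCorrectNormalize(simulateCestDynamics(ph, sched), sched)
  mk <- function(s) new("B0Map", shift = matrix(s, 16, 16),
                        fitQuality = matrix(0, 16, 16), mask = zMask(zs),
                        flat = matrix(FALSE, 16, 16))
  back <- recenterSpectra(recenterSpectra(zs, mk(0.15)), mk(-0.15))
  keep <- abs(zOffsets(zs)) <= 4.5
  m <- as.vector(zMask(zs))
  expect_lt(max(abs(zValues(back)[m, keep] - zValues(zs)[m, keep]),
                na.rm = TRUE), 1e-3)
})

test_that("AFI inversion is the algebraic inverse of the forward model", {
  ph <- fixturePhantom(gridSize = 12)
  afi <- simulateAfiPair(ph, tr1 = 35, tr2 = 160, nominalFlip = 60)
  b1 <- computeAfiB1(afi$s1, afi$s2, 35, 160, 60, mask = afi$mask)
  expect_lt(max(abs(relativeFlip(b1)[mapMask(b1)] - 1)), 1e-9)

  # across the (5, 90) degree range via the b1 field
  for (scale in c(0.2, 0.5, 0.9, 1.3)) {
    phs <- buildPhantom(defaultTissueTable(), gridSize = 12,
                        b1 = list(mode = "constant", value = scale),
                        noiseSd = 0, seed = 2)
    a <- simulateAfiPair(phs, nominalFlip = 60)
    b <- computeAfiB1(a$s1, a$s2, mask = a$mask)
    expect_lt(max(abs(relativeFlip(b)[mapMask(b)] - scale)), 1e-6)
  }
})

test_that("AFI recovers a 10 percent transmit deficit within 0.1 degree", {
  ph <- buildPhantom(defaultTissueTable(), gridSize = 12,
                     b1 = list(mode = "constant", value = 0.9),
                     noiseSd = 0, seed = 2)
  a <- simulateAfiPair(ph, nominalFlip = 60)
  b <- computeAfiB1(a$s1, a$s2, nominalFlip = 60, mask = a$mask)
  flips <- relativeFlip(b)[mapMask(b)] * 60
  expect_lt(max(abs(flips - 54)), 0.1)
})

test_that("degenerate AFI ratios are handled", {
  s1 <- matrix(c(1, 1), 2, 1)
  s2 <- matrix(c(1, 0.1), 2, 1)  # r = 1 -> alpha = 0; r = 0.1 < 1/n invalid
  b <- computeAfiB1(s1, s2, 35, 160, 60)
  expect_false(b@mask[1, 1])  # alpha = 0 is outside (0, 2) relative flip
  expect_false(b@mask[2, 1])
  # the closed form itself: r = 1 gives cos(alpha) = 1
  n <- 160 / 35
  expect_equal((1 * n - 1) / (n - 1), 1)
})
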