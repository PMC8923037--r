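test_that("phantom construction is deterministic and validated", {
  ph1 <- fixturePhantom(noiseSd = 0.01, seed = 7)
  ph2 <- fixturePhantom(noiseSd = 0.01, seed = 7)
  expect_identical(ph1, ph2)
  d1 <- simulateCestDynamics(ph1, canonicalSchedule())
  d2 <- simulateCestDynamics(ph2, canonicalSchedule())
  expect_identical(d1, d2)
  # invalid class: pool amplitudes >= zBase names the class
  expect_error(tissueClass("GM", list(poolSpec("DS", 0.7, 2, 0),
                                      poolSpec("MT", 0.4, 50, -2.4)),
                           r1 = 1),
               "GM")
  expect_error(buildPhantom(gridSize = 4), "n >= 8")
})

test_that("zero-noise simulation equals the analytic forward model", {
  ph <- fixturePhantom(noiseSd = 0)
  sched <- canonicalSchedule()
  dyn <- simulateCestDynamics(ph, sched, s0 = 1000)
  off <- scheduleOffsets(sched)
  ztrue <- trueZSpectrum(ph, off)
  satIdx <- saturatedIndices(sched) + 1L
  tissue <- as.vector(labelMap(ph)) > 0
  for (k in c(1L, 20L, 43L)) {
    img <- as.vector(dyn[, , satIdx[k]])
    expect_equal(img[tissue], 1000 * ztrue[tissue, k], tolerance = 1e-12)
  }
  # reference dynamics carry the bare (undrifted) signal
  refIdx <- referenceIndices(sched) + 1L
  expect_equal(as.vector(dyn[, , refIdx[1]])[tissue],
               rep(1000, sum(tissue)))
})

test_that("independently computed forward model confirms the simulator", {
  ph <- fixturePhantom(noiseSd = 0, b0 = list(mode = "constant", value = 0.1))
  off <- c(-3, -2.4, 0, 0.1, 3)
  z <- trueZSpectrum(ph, off)
  i <- which(as.vector(tissueMask(ph, "GM")))[1]
  expected <- 1 -
    refLorentz(0.60, 2.55, 0, off - 0.1) -
    refLorentz(0.10, 55, -2.4, off - 0.1) -
    refLorentz(0.030, 1.5, 3.0, off - 0.1)
  expect_equal(z[i, ], expected, tolerance = 1e-12)
  # spectrum minimum sits at the B0 shift (up to a ~0.001 ppm tilt from
  # the asymmetric MT tail under the water dip)
  fine <- seq(-0.5, 0.5, by = 0.001)
  zf <- trueZSpectrum(ph, fine)[i, ]
  expect_equal(fine[which.min(zf)], 0.1, tolerance = 0.02)
})

test_that("drift profile is reproduced exactly in noiseless references", {
  ph <- fixturePhantom(noiseSd = 0,
                       drift = list(type = "linear", from = 1.0, to = 0.95))
  sched <- canonicalSchedule()
  dyn <- simulateCestDynamics(ph, sched, s0 = 1)
  i <- which(tissueMask(ph, "WM"), arr.ind = TRUE)[1, ]
  s0series <- dyn[i[1], i[2], referenceIndices(sched) + 1L]
  expect_equal(s0series,
               seq(1.0, 0.95, length.out = 56)[referenceIndices(sched) + 1L],
               tolerance = 1e-12)
})

test_that("increasing the amine amplitude deepens saturation at +3 ppm", {
  amps <- c(0.01, 0.02, 0.04)
  z3 <- vapply(amps, function(a) {
    ph <- fixturePhantom(amine = a)
    z <- trueZSpectrum(ph, 3.0)
    mean(z[as.vector(labelMap(ph) > 0)])
  }, numeric(1))
  expect_true(all(diff(z3) < 0))
})

test_that("IR simulation obeys closed-form limits", {
  ph <- fixturePhantom()
  # long-TI recovery: at TI = 8000 ms with R1 = 1/s the residual
  # inversion term is e^-8
  tt <- defaultTissueTable()
  tt$WM@r1 <- 1.0
  ph@tissues <- tt
  ir <- simulateIrSeries(ph, tiList = c(6, 100, 8000), invEfficiency = 1)
  i <- which(ir$labelMaps[, , 3] == 2L, arr.ind = TRUE)[1, ]
  expect_equal(ir$series[i[1], i[2], 3, 3] / 1000, abs(1 - 2 * exp(-8)),
               tolerance = 1e-12)
  # null point at TI = ln 2 / R1 for perfect inversion
  tiNull <- log(2) / 1.0 * 1000
  irn <- simulateIrSeries(ph, tiList = c(6, tiNull, 8000),
                          invEfficiency = 1)
  expect_equal(irn$series[i[1], i[2], 3, 2], 0, tolerance = 1e-9)
  expect_error(simulateIrSeries(ph, tiList = c(10, 10, 20)), "increasing")
})

test_that("AFI pair reproduces the dual-TR ratio identity", {
  ph <- fixturePhantom(gridSize = 12)
  afi <- simulateAfiPair(ph, tr1 = 35, tr2 = 160, nominalFlip = 60)
  n <- 160 / 35
  tissue <- afi$mask
  r <- (afi$s2 / afi$s1)[tissue]
  alpha <- 60 * pi / 180
  expect_equal(r, rep((1 + n * cos(alpha)) / (n + cos(alpha)), sum(tissue)),
               tolerance = 1e-12)
  # small-flip limit: ratio tends to 1
  ph2 <- fixturePhantom(gridSize = 12)
  afi2 <- simulateAfiPair(ph2, nominalFlip = 0.01)
  expect_equal(max(abs((afi2$s2 / afi2$s1)[afi2$mask] - 1)), 0,
               tolerance = 1e-6)
  expect_error(simulateAfiPair(ph, tr1 = 100, tr2 = 50), "TR2 > TR1")
})
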