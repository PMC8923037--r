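# Contrast arithmetic, the AREX identity, and isolation properties.

test_that("contrast arithmetic matches hand-computed values", {
  off <- c(-5, -4, -3, -2, -1, 0, 1, 2, 3, 4, 5)
  # one voxel with Z(-3) = 0.90, Z(+3) = 0.85
  z <- matrix(c(0.95, 0.92, 0.90, 0.80, 0.60, 0.40, 0.60, 0.80, 0.85,
                0.92, 0.95), 1)
  st <- stackFromValues(z, off)
  expect_equal(legacyGlucest(st, 3)[1, 1], 100 * (0.90 - 0.85) / 0.90)
  expect_equal(legacyGlucest(st, 3)[1, 1], 5.5556, tolerance = 1e-4)
  expect_equal(computeMtrAsymCorr(st, 3)[1, 1], 0.05)
  expect_equal(computeMtrAsymCorr(st, 0)[1, 1], 0)
  # inverse difference on corrected values 0.85/0.90
  expect_equal(1 / 0.85 - 1 / 0.90, 0.06536, tolerance = 1e-4)

  # symmetric spectrum: all asymmetry contrasts vanish
  zs <- matrix(c(0.95, 0.9, 0.85, 0.8, 0.6, 0.4, 0.6, 0.8, 0.85, 0.9,
                 0.95), 1)
  sts <- stackFromValues(zs, off)
  expect_equal(legacyGlucest(sts, 3)[1, 1], 0)
  expect_equal(computeMtrAsymCorr(sts, 3)[1, 1], 0)
})

test_that("AREX is exactly the elementwise product with R1", {
  rex <- matrix(c(0.06536, 0, 0.1, NA), 2, 2)
  r1 <- matrix(c(1, 2, 0.5, 1), 2, 2)
  arex <- computeArexCorr(rex, r1)
  expect_identical(arex, rex * r1)
  expect_equal(arex[1, 1], 0.06536)
  expect_equal(arex[2, 1], 0)              # zero contrast stays zero
  expect_equal(computeArexCorr(rex, r1 / 2)[1, 1], arex[1, 1] / 2)
  # invalid R1 propagates
  r1bad <- r1; r1bad[1, 2] <- -1
  expect_true(is.na(computeArexCorr(rex, r1bad)[1, 2]))
})

test_that("phantoms without an amine pool give null corrected contrasts", {
  ph <- fixturePhantom(amine = 0)
  sched <- canonicalSchedule()
  zs <- driftCorrectNormalize(simulateCestDynamics(ph, sched), sched)
  fits <- fitTwoPoolStack(zs)
  cm <- computeContrastMaps(zs, fits, matrix(1, 16, 16))
  expect_lt(max(abs(mtrRexCorr(cm)[cm@mask])), 1e-4)
  expect_lt(max(abs(mtrAsymCorr(cm)[cm@mask])), 1e-4)
  expect_lt(max(abs(arexCorr(cm)[cm@mask])), 1e-4)
})

test_that("doubling a small amine amplitude about doubles MTR_RexCorr", {
  rexAt <- function(a) {
    ph <- fixturePhantom(gridSize = 12, amine = a, seed = 4)
    sched <- canonicalSchedule()
    zs <- driftCorrectNormalize(simulateCestDynamics(ph, sched), sched)
    rex <- computeMtrRexCorr(zs, fitTwoPoolStack(zs))
    mean(rex[tissueMask(ph, "GM")], na.rm = TRUE)
  }
  amps <- c(0.01, 0.02, 0.04)
  vals <- vapply(amps, rexAt, numeric(1))
  expect_true(all(diff(vals) > 0))          # monotone in amplitude
  ratio <- vals[3] / vals[2]
  expect_gte(ratio, 1.8)
  expect_lte(ratio, 2.2)
})

test_that("AREX preserves the GM > WM amine ordering and MT removal
           shrinks the uncorrected tissue difference", {
  ph <- fixturePhantom()  # GM amine 0.030 > WM amine 0.020; MT differs too
  sched <- canonicalSchedule()
  zs <- driftCorrectNormalize(simulateCestDynamics(ph, sched), sched)
  fits <- fitTwoPoolStack(zs)
  r1m <- matrix(r1TruthByClass(ph)[labelMap(ph) + 1L], 16, 16)
  cm <- computeContrastMaps(zs, fits, r1m)
  gm <- tissueMask(ph, "GM") & cm@mask
  wm <- tissueMask(ph, "WM") & cm@mask
  expect_gt(mean(arexCorr(cm)[gm]), mean(arexCorr(cm)[wm]))

  # uncorrected asymmetry difference (driven by MT) exceeds corrected
  uncorr <- sampleStackAtOffset(zs, -3) - sampleStackAtOffset(zs, 3)
  corr <- mtrAsymCorr(cm)
  dU <- abs(mean(uncorr[gm]) - mean(uncorr[wm]))
  dC <- abs(mean(corr[gm]) - mean(corr[wm]))
  expect_lt(dC, dU)

  # MT removal shifts asymmetry toward positive values
  expect_gt(mean(corr[wm]), mean(uncorr[wm]))
  expect_gt(mean(corr[gm]), mean(uncorr[gm]))
})

test_that("the inverse-space variant is computed and flagged", {
  ph <- fixturePhantom()
  sched <- canonicalSchedule()
  zs <- driftCorrectNormalize(simulateCestDynamics(ph, sched), sched)
  fits <- fitTwoPoolStack(zs)
  rex <- computeMtrRexCorr(zs, fits, variant = "inverse_space_subtraction")
  expect_equal(attr(rex, "variant"), "inverse_space_subtraction")
  expect_true(any(is.finite(rex)))
  rexZ <- computeMtrRexCorr(zs, fits)
  expect_false(isTRUE(all.equal(rex[zMask(zs)], rexZ[zMask(zs)])))
})
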