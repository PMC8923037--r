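# Lorentzian line shape, the bounded two-pool fit, and MT removal.

test_that("line shape has the right peak, FWHM, and limits", {
  expect_equal(lorentzian(0.35, 55, -2.4, -2.4), 0.35)
  expect_equal(lorentzian(0.35, 55, -2.4, -2.4 + 55 / 2), 0.35 / 2)
  expect_equal(lorentzian(0.35, 55, -2.4, -2.4 - 55 / 2), 0.35 / 2)
  expect_equal(lorentzian(0, 2, 0, seq(-5, 5)), rep(0, 11))
  expect_error(lorentzian(0.5, -1, 0, 0), "sigma")
  # evenness of the DS component about its center
  w <- seq(0.2, 5, by = 0.2)
  expect_equal(lorentzian(0.6, 2.55, 0, w), lorentzian(0.6, 2.55, 0, -w))
})

test_that("noiseless spectra are recovered to high precision", {
  off <- scheduleOffsets(canonicalSchedule())
  z <- refTwoPool(0.60, 2.55, 0.35, 55, off)
  f <- fitTwoPool(z, off)
  expect_true(f$converged)
  truth <- c(dsA = 0.60, dsW = 2.55, mtA = 0.35, mtW = 55)
  expect_lt(max(abs(f$params[names(truth)] - truth) / truth), 1e-6)
  expect_lt(f$residRms, 1e-10)
})

test_that("flat spectra pin the DS amplitude at its lower bound", {
  off <- scheduleOffsets(canonicalSchedule())
  f <- fitTwoPool(rep(1, length(off)), off)
  expect_equal(unname(f$params["dsA"]), 0.20, tolerance = 1e-9)
  expect_true(f$atBound)
})

test_that("insufficient or one-sided spectra are rejected", {
  off <- seq(0.5, 5, by = 0.5)
  expect_error(fitTwoPool(rep(0.8, 10), off), "spanning")
  expect_error(fitTwoPool(rep(0.8, 5), seq(-5, 5, length.out = 5)), "10")
})

test_that("bounded fit matches an exhaustive grid-search oracle", {
  toys <- list(c(0.60, 0.35, 2.60, 55), c(0.40, 0.10, 1.60, 30),
               c(0.80, 0.50, 3.10, 70), c(0.30, 0.15, 0.85, 20),
               c(0.55, 0.25, 2.10, 45))
  offT <- c(-5, -4, -3, -2.4, -1, 0, 1, 2.4, 3, 4, 5)
  for (tp in toys) {
    z <- refTwoPool(tp[1], tp[3], tp[2], tp[4], offT)
    fit <- fitTwoPool(z, offT)
    oracle <- gridOracleTwoPool(z, offT)
    expect_lte(abs(fit$params["dsA"] - oracle["dsA"]), 0.005)
    expect_lte(abs(fit$params["mtA"] - oracle["mtA"]), 0.005)
    expect_lte(abs(fit$params["dsW"] - oracle["dsW"]), 0.25)
    expect_lte(abs(fit$params["mtW"] - oracle["mtW"]), 0.25)
  }
})

test_that("random in-bounds truths are recovered; noise stays controlled", {
  off <- scheduleOffsets(canonicalSchedule())
  set.seed(11)
  nOk <- 0
  for (rep in 1:60) {
    dsA <- runif(1, 0.25, 0.88)
    truth <- c(dsA = dsA, mtA = runif(1, 0.02, min(0.85, 0.93 - dsA)),
               dsW = runif(1, 0.8, 4.5), mtW = runif(1, 15, 95))
    z <- refTwoPool(truth["dsA"], truth["dsW"], truth["mtA"], truth["mtW"],
                    off)
    zn <- z + rnorm(length(off), 0, 0.005)
    fn <- fitTwoPool(zn, off)
    nOk <- nOk + (abs(fn$params["dsA"] - truth["dsA"]) <= 0.01) +
      (abs(fn$params["mtA"] - truth["mtA"]) <= 0.01)
  }
  # median amplitude error under 0.5% noise is well below 0.01
  expect_gt(nOk / 120, 0.5)
})

test_that("fitted MT component peaks at -2.4 ppm with fixed center", {
  off <- scheduleOffsets(canonicalSchedule())
  z <- refTwoPool(0.5, 2.0, 0.3, 40, off)
  f <- fitTwoPool(z, off)
  expect_equal(unname(mtBaseline(f$params, -2.4)),
               unname(f$params["mtA"]), tolerance = 1e-12)
  expect_equal(unname(mtBaseline(f$params, -2.4 + f$params[["mtW"]] / 2)),
               unname(f$params["mtA"] / 2), tolerance = 1e-12)
  expect_equal(mtBaseline(c(mtA = 0, mtW = 40), off), rep(0, length(off)))
})

test_that("MT removal restores the DS-only spectrum and is an identity at
           zero MT", {
  ph <- fixturePhantom(amine = 0)
  sched <- canonicalSchedule()
  zs <- driftCorrectNormalize(simulateCestDynamics(ph, sched), sched)
  fits <- fitTwoPoolStack(zs)
  zc <- subtractMt(zs, fits)
  for (lab in c("GM", "WM")) {
    i <- which(as.vector(tissueMask(ph, lab)))[1]
    tc <- tissueClasses(ph)[[lab]]
    ds <- tc@pools[[1]]
    truth <- 1 - refLorentz(ds@amplitude, ds@width, 0, zOffsets(zc))
    expect_lt(max(abs(zValues(zc)[i, ] - truth)), 1e-8)
  }
  # CSF has no MT: corrected spectrum equals measured there (fitted MT ~ 0)
  iCsf <- which(as.vector(tissueMask(ph, "CSF")))[1]
  expect_lt(max(abs(zValues(zc)[iCsf, ] - zValues(zs)[iCsf, ])), 1e-8)
})

test_that("a small amine pool leaves the reference side of Zcorr nearly
           unchanged", {
  # reference-side isolation in the small-amplitude regime: the amine dip
  # at +3 ppm must barely perturb the corrected spectrum at -3 ppm, while
  # moving the +3 ppm side by an order of magnitude more. (With larger
  # amine amplitudes the two-pool fit absorbs part of the solute dip into
  # the MT pool and the leakage grows; see the methods vignette.)
  off <- scheduleOffsets(canonicalSchedule())
  z0 <- refTwoPool(0.60, 2.55, 0.10, 55, off)
  z1 <- z0 - refLorentz(0.01, 1.5, 3.0, off)
  zc <- function(z) z + mtBaseline(fitTwoPool(z, off)$params, off)
  c0 <- zc(z0); c1 <- zc(z1)
  refSide <- abs(c1[off == -3] - c0[off == -3])
  targetSide <- abs(c1[off == 3] - c0[off == 3])
  expect_lt(refSide, 1e-3)
  expect_gt(targetSide, 5 * refSide)
})

test_that("MT removal shrinks GM-WM spectral separation when only MT
           differs", {
  tt <- defaultTissueTable(amineScale = 0)
  # GM and WM identical except MT amplitude
  tt$GM <- tissueClass("GM", list(poolSpec("DS", 0.55, 2.3, 0),
                                  poolSpec("MT", 0.10, 55, -2.4)), r1 = 0.5)
  tt$WM <- tissueClass("WM", list(poolSpec("DS", 0.55, 2.3, 0),
                                  poolSpec("MT", 0.25, 55, -2.4)), r1 = 0.83)
  ph <- buildPhantom(tt, gridSize = 16, noiseSd = 0, seed = 3,
                     drift = list(type = "constant", value = 1))
  sched <- canonicalSchedule()
  zs <- driftCorrectNormalize(simulateCestDynamics(ph, sched), sched)
  zc <- subtractMt(zs, fitTwoPoolStack(zs))
  sep <- function(stack) {
    g <- colMeans(zValues(stack)[as.vector(tissueMask(ph, "GM")), ])
    w <- colMeans(zValues(stack)[as.vector(tissueMask(ph, "WM")), ])
    mean(abs(g - w))
  }
  expect_lt(sep(zc), sep(zs))
})
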