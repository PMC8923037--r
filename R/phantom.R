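# Synthetic phantom generator: pre-aligned CEST/WASSR/AFI/IR acquisitions
# with fully known ground truth.

# Run expr with a private RNG stream; global .Random.seed is untouched.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Default tissue-class table for the brain-slice phantom
#'
#' Per-class pool parameters (direct saturation at 0 ppm, broad semisolid MT
#' at -2.4 ppm, amine pool at +3.0 ppm, optional relayed NOE near -3.5 ppm)
#' and free-water R1 values chosen from typical 7T literature ranges: WM
#' carries the largest MT fraction (myelin), GM a larger amine amplitude
#' than WM (higher glutamate concentration), CSF almost no MT, and the WM
#' lesion class a reduced MT (demyelination) with an amine amplitude equal
#' to WM unless elevated via `wmLesionAmineBoost`.
#'
#' @param includeRnoe add an rNOE pool at -3.5 ppm to every parenchymal
#'   class (model-mismatch robustness studies)
#' @param wmLesionAmineBoost additive increase of the WM-lesion amine
#'   amplitude over normal WM (fraction of Z)
#' @param amineScale multiplies every amine amplitude (effect-size studies)
#' @return named list of [TissueClass-class] objects in label-index order
#'   (`GM`, `WM`, `CSF`, `WM_lesion`, `cortical_lesion`)
#' @export
defaultTissueTable <- function(includeRnoe = FALSE, wmLesionAmineBoost = 0,
                               amineScale = 1) {
  mk <- function(label, dsA, dsW, mtA, mtW, amA, amW, r1) {
    pools <- list(poolSpec("DS", dsA, dsW, 0),
                  poolSpec("MT", mtA, mtW, -2.4),
                  poolSpec("amine", amA * amineScale, amW, 3.0))
    if (includeRnoe)
      pools <- c(pools, list(poolSpec("rNOE", 0.02, 3.0, -3.5)))
    tissueClass(label, pools, zBase = 1.0, r1 = r1)
  }
  list(
    GM = mk("GM", 0.60, 2.55, 0.10, 55, 0.030, 1.5, 0.50),
    WM = mk("WM", 0.55, 2.30, 0.25, 55, 0.020, 1.5, 0.83),
    CSF = mk("CSF", 0.85, 1.40, 0.00, 55, 0.005, 1.5, 0.23),
    WM_lesion = mk("WM_lesion", 0.55, 2.30, 0.18, 55,
                   0.020 + wmLesionAmineBoost, 1.5, 0.70),
    cortical_lesion = mk("cortical_lesion", 0.60, 2.55, 0.08, 55,
                         0.030, 1.5, 0.55))
}

# Concentric-geometry label map: CSF core, WM ring, GM rim, background
# border, one WM lesion disc and one cortical lesion disc. radiusJitter
# perturbs the ring boundaries (used for the thin IR slices).
makeLabelMap <- function(n, radiusJitter = 0) {
  stopifnot(n >= 8)
  cx <- (n + 1) / 2
  xy <- expand.grid(x = seq_len(n), y = seq_len(n))
  r <- sqrt((xy$x - cx)^2 + (xy$y - cx)^2) / n
  lab <- integer(n * n)                      # 0 = background
  lab[r <= 0.45 + radiusJitter] <- 1L        # GM rim
  lab[r <= 0.32 + radiusJitter] <- 2L        # WM
  lab[r <= 0.10 + radiusJitter] <- 3L        # CSF core
  # WM lesion: disc centered in the WM ring, upper right
  lr <- sqrt((xy$x - (cx + 0.20 * n))^2 + (xy$y - (cx + 0.08 * n))^2) / n
  lab[lr <= 0.06 + radiusJitter & lab == 2L] <- 4L
  # cortical lesion: small disc in the GM rim, lower left
  cr <- sqrt((xy$x - (cx - 0.36 * n))^2 + (xy$y - (cx - 0.12 * n))^2) / n
  lab[cr <= 0.04 + radiusJitter & lab == 1L] <- 5L
  matrix(lab, n, n)
}

#' Build a synthetic phantom with known ground truth
#'
#' Constructs a 2D single-slice phantom (concentric CSF/WM/GM geometry with
#' one WM and one cortical lesion) carrying per-voxel pool parameters, a
#' smooth B0 inhomogeneity field, a relative-transmit B1 field, a
#' multiplicative S0 drift profile and a noise level. Deterministic given
#' `(config, seed)`.
#'
#' @param tissueTable named list of [TissueClass-class] (see
#'   [defaultTissueTable()]); order defines the label indices
#' @param gridSize slice is `gridSize x gridSize`; at least 8
#' @param b0 list: `mode = "constant"` with `value` (ppm), or
#'   `mode = "smooth"` with `amplitude` (ppm, peak of a low-order harmonic
#'   surface; must stay within +/-0.3 by default usage)
#' @param b1 list: `mode = "constant"` with `value`, or `mode = "smooth"`
#'   with `center` and `amplitude` (relative transmit scale)
#' @param drift list: `type = "constant"` (no drift) or `type = "linear"`
#'   with `from`/`to` multiplicative factors over the dynamic series
#' @param noiseSd additive noise SD as a fraction of the unsaturated signal
#' @param noiseModel `"gaussian"` or `"rician"`
#' @param seed integer seed recorded in the truth and used by simulators
#' @return a [PhantomTruth-class]
#' @examples
#' ph <- buildPhantom(gridSize = 32, noiseSd = 0, seed = 1)
#' table(labelMap(ph))
#' @export
buildPhantom <- function(tissueTable = defaultTissueTable(), gridSize = 64,
                         b0 = list(mode = "constant", value = 0),
                         b1 = list(mode = "constant", value = 1),
                         drift = list(type = "linear", from = 1.0, to = 0.97),
                         noiseSd = 0.005, noiseModel = "gaussian",
                         seed = 1L) {
  for (tc in tissueTable) validObject(tc)
  lab <- makeLabelMap(gridSize)
  n <- gridSize
  xy <- expand.grid(x = seq_len(n), y = seq_len(n))
  b0f <- switch(b0$mode,
    constant = matrix(b0$value, n, n),
    smooth = matrix(b0$amplitude *
                      sin(pi * xy$x / n) * cos(pi * xy$y / n), n, n),
    stop("unknown b0 mode: ", b0$mode))
  b1f <- switch(b1$mode,
    constant = matrix(b1$value, n, n),
    smooth = matrix(b1$center + b1$amplitude *
                      cos(pi * xy$x / n) * sin(pi * xy$y / n), n, n),
    stop("unknown b1 mode: ", b1$mode))
  new("PhantomTruth", labelMap = lab, tissues = tissueTable, b0Field = b0f,
      b1Field = b1f, drift = drift, noiseSd = noiseSd,
      noiseModel = noiseModel, seed = as.integer(seed))
}

#' Multiplicative drift factor per dynamic
#'
#' @param phantom a [PhantomTruth-class]
#' @param nDyn number of dynamics in the series
#' @return numeric vector of length `nDyn`, all > 0
#' @export
driftVector <- function(phantom, nDyn) {
  d <- phantom@drift
  v <- switch(d$type,
    constant = rep(if (is.null(d$value)) 1 else d$value, nDyn),
    linear = seq(d$from, d$to, length.out = nDyn),
    stop("unknown drift type: ", d$type))
  if (any(v <= 0)) stop("drift profile must be positive")
  v
}

#' Analytic ground-truth z-spectrum
#'
#' Evaluates the multi-pool forward model `Z = zBase - sum_i L_i(offset -
#' b0)` for every voxel at the given offsets, using the per-voxel B0 shift.
#' Background voxels return `NA`.
#'
#' @param phantom a [PhantomTruth-class]
#' @param offsets numeric vector of offsets, ppm
#' @return matrix, `prod(dim(labelMap))` rows (column-major voxel order) by
#'   `length(offsets)` columns
#' @export
trueZSpectrum <- function(phantom, offsets) {
  lab <- as.vector(phantom@labelMap)
  b0 <- as.vector(phantom@b0Field)
  out <- matrix(NA_real_, length(lab), length(offsets))
  for (k in seq_along(phantom@tissues)) {
    idx <- which(lab == k)
    if (!length(idx)) next
    tc <- phantom@tissues[[k]]
    # effective offset seen by voxel i at column j: offsets[j] - b0[i]
    w <- outer(-b0[idx], offsets, `+`)
    z <- matrix(tc@zBase, length(idx), length(offsets))
    for (p in tc@pools)
      z <- z - p@amplitude / (1 + 4 * ((w - p@center) / p@width)^2)
    out[idx, ] <- z
  }
  out
}

# Additive (or Rician) noise on a signal array, SD in absolute units.
addNoise <- function(x, sd, model) {
  if (sd <= 0) return(x)
  if (model == "gaussian") return(x + rnorm(length(x), 0, sd))
  sqrt((x + rnorm(length(x), 0, sd))^2 + rnorm(length(x), 0, sd)^2)
}

#' Simulate the raw CEST dynamic series
#'
#' Produces saturated and unsaturated images in acquisition order:
#' `S(t) = drift(t) * S0 * Z_true(offset)` for saturated dynamics and
#' `S(t) = drift(t) * S0` for references, plus additive noise of SD
#' `noiseSd * S0`. Background voxels receive pure noise around a small
#' pedestal.
#'
#' @param phantom a [PhantomTruth-class]
#' @param schedule an [OffsetSchedule-class]
#' @param seed integer; every simulator takes an explicit seed
#' @param s0 unsaturated tissue signal level (arbitrary units)
#' @return 3D array `(x, y, dynamic)` with the schedule attached as
#'   attribute `"schedule"`
#' @export
simulateCestDynamics <- function(phantom, schedule, seed = phantom@seed,
                                 s0 = 1000) {
  validObject(phantom)
  e <- schedule@entries
  nDyn <- nrow(e)
  d <- dim(phantom@labelMap)
  drift <- driftVector(phantom, nDyn)
  ztrue <- trueZSpectrum(phantom, e$offset_ppm[!e$is_reference])
  tissue <- as.vector(phantom@labelMap) > 0L
  base <- ifelse(tissue, s0, 0.01 * s0)   # faint background pedestal
  out <- array(NA_real_, c(d, nDyn))
  satCol <- 0L
  withSeed(seed, {
    for (t in seq_len(nDyn)) {
      if (e$is_reference[t]) {
        img <- drift[t] * base
      } else {
        satCol <- satCol + 1L
        z <- ztrue[, satCol]
        z[!tissue] <- 1
        img <- drift[t] * base * z
      }
      out[, , t] <- addNoise(img, phantom@noiseSd * s0, phantom@noiseModel)
    }
  })
  attr(out, "schedule") <- schedule
  out
}

#' Simulate the WASSR dynamic series
#'
#' Low-power acquisition showing only a narrow direct-saturation dip,
#' shifted per voxel by the phantom's B0 field. Uses the same raw-dynamics
#' layout as [simulateCestDynamics()] so the series can be assembled with
#' [driftCorrectNormalize()]. If the schedule does not cover the phantom's
#' true shifts (plus half the dip width), attribute `"coverage_warning"` is
#' set.
#'
#' @param phantom a [PhantomTruth-class]
#' @param schedule WASSR [OffsetSchedule-class]; must span at least
#'   +/-1.0 ppm
#' @param seed integer
#' @param dipAmplitude,dipWidth amplitude (fraction) and FWHM (ppm) of the
#'   low-power water dip
#' @param s0 unsaturated signal level
#' @return 3D array `(x, y, dynamic)`
#' @export
simulateWassr <- function(phantom, schedule = wassrSchedule(),
                          seed = phantom@seed + 1L, dipAmplitude = 0.8,
                          dipWidth = 0.4, s0 = 1000) {
  off <- scheduleOffsets(schedule)
  if (max(off) < 1.0 || min(off) > -1.0)
    stop("WASSR schedule must span at least +/-1.0 ppm around 0")
  # DS-only phantom sharing geometry/fields/noise with the parent
  tissues <- lapply(phantom@tissues, function(tc) {
    if (tc@label == "background") return(tc)
    tissueClass(tc@label, list(poolSpec("DS", dipAmplitude, dipWidth, 0)),
                zBase = 1.0, r1 = tc@r1)
  })
  dsPhantom <- new("PhantomTruth", labelMap = phantom@labelMap,
                   tissues = tissues, b0Field = phantom@b0Field,
                   b1Field = phantom@b1Field,
                   drift = list(type = "constant", value = 1),
                   noiseSd = phantom@noiseSd, noiseModel = phantom@noiseModel,
                   seed = as.integer(seed))
  out <- simulateCestDynamics(dsPhantom, schedule, seed = seed, s0 = s0)
  margin <- max(abs(phantom@b0Field)) + dipWidth / 2
  if (max(off) < margin || abs(min(off)) < margin)
    attr(out, "coverage_warning") <-
      "WASSR schedule may not cover the phantom's B0 shifts"
  out
}

#' Simulate the inversion-recovery series
#'
#' Magnitude IR signal `|m0 (1 - (1 + e) exp(-TI R1))|` per voxel, with
#' inversion efficiency `e` (1 = perfect inversion). Five thin slices are
#' generated by default with slightly perturbed tissue boundaries so the
#' slice-collapsing rules are exercised; slice 3 matches the CEST slice
#' geometry exactly.
#'
#' @param phantom a [PhantomTruth-class]
#' @param tiList inversion times in ms, strictly increasing
#' @param seed integer
#' @param invEfficiency inversion efficiency in (0, 1]
#' @param nSlices number of thin slices
#' @param m0 equilibrium signal level
#' @return list with `series` (4D array `(x, y, slice, TI)`), `labelMaps`
#'   (3D integer array `(x, y, slice)`), `tiList`
#' @export
simulateIrSeries <- function(phantom, tiList = canonicalTiList(),
                             seed = phantom@seed + 2L, invEfficiency = 1,
                             nSlices = 5L, m0 = 1000) {
  if (any(diff(tiList) <= 0) || any(tiList <= 0))
    stop("tiList must be positive and strictly increasing")
  n <- dim(phantom@labelMap)[1]
  jit <- seq(-0.02, 0.02, length.out = nSlices)
  labs <- vapply(jit, function(j) makeLabelMap(n, j), phantom@labelMap)
  r1ByClass <- c(NA_real_, vapply(phantom@tissues, function(t) t@r1,
                                  numeric(1)))
  series <- array(NA_real_, c(n, n, nSlices, length(tiList)))
  withSeed(seed, {
    for (s in seq_len(nSlices)) {
      r1 <- matrix(r1ByClass[labs[, , s] + 1L], n, n)
      for (k in seq_along(tiList)) {
        sig <- abs(m0 * (1 - (1 + invEfficiency) *
                           exp(-tiList[k] / 1000 * r1)))
        sig[is.na(sig)] <- 0.01 * m0
        series[, , s, k] <- addNoise(sig, phantom@noiseSd * m0,
                                     phantom@noiseModel)
      }
    }
  })
  list(series = series, labelMaps = labs, tiList = tiList)
}

#' The protocol inversion-time list
#'
#' @return the 14 inversion times of the IR protocol, in ms
#' @export
canonicalTiList <- function()
  c(6, 10, 16, 26, 42, 68, 110, 178, 288, 468, 760, 1233, 2000, 8000)

#' Simulate a dual-TR AFI image pair
#'
#' Ideal actual-flip-angle-imaging steady-state signals in the short-TR
#' regime, constructed so that `S2/S1 = (1 + n cos a)/(n + cos a)` with
#' `n = TR2/TR1` and actual flip `a = nominalFlip * b1Field`.
#'
#' @param phantom a [PhantomTruth-class]
#' @param tr1,tr2 repetition times in ms, `tr2 > tr1 > 0`
#' @param nominalFlip nominal flip angle, degrees
#' @param seed integer
#' @param s0 signal scale
#' @return list with matrices `s1`, `s2` and the parameters
#' @export
simulateAfiPair <- function(phantom, tr1 = 35, tr2 = 160, nominalFlip = 60,
                            seed = phantom@seed + 3L, s0 = 1000) {
  if (!(tr2 > tr1 && tr1 > 0)) stop("need TR2 > TR1 > 0")
  n <- tr2 / tr1
  alpha <- nominalFlip * phantom@b1Field * pi / 180
  tissue <- phantom@labelMap > 0L
  s1 <- s0 * sin(alpha) * (n + cos(alpha)) / (n + 1)
  s2 <- s0 * sin(alpha) * (1 + n * cos(alpha)) / (n + 1)
  s1[!tissue] <- 0.01 * s0
  s2[!tissue] <- 0.01 * s0
  withSeed(seed, {
    s1 <- addNoise(s1, phantom@noiseSd * s0, phantom@noiseModel)
    s2 <- addNoise(s2, phantom@noiseSd * s0, phantom@noiseModel)
  })
  list(s1 = s1, s2 = s2, tr1 = tr1, tr2 = tr2, nominalFlip = nominalFlip,
       mask = tissue)
}
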