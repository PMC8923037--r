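#' @import methods
#' @importFrom stats splinefun optimize median quantile rnorm runif t.test
#'   lm resid cor pt complete.cases setNames
#' @importFrom utils read.delim write.table modifyList
NULL

# ---------------------------------------------------------------------------
# OffsetSchedule
# ---------------------------------------------------------------------------

#' Saturation-offset acquisition schedule
#'
#' An `OffsetSchedule` records the acquisition order of a CEST (or WASSR)
#' dynamic series: for every dynamic, either the saturation offset in ppm or
#' a marker that the dynamic is an unsaturated reference (S0) image.
#'
#' @slot entries a `data.frame` with columns `index` (0-based acquisition
#'   index, contiguous), `offset_ppm` (numeric, `NA` for references) and
#'   `is_reference` (logical).
#'
#' @seealso [offsetSchedule()], [canonicalSchedule()], [wassrSchedule()]
#' @export
setClass("OffsetSchedule", representation(entries = "data.frame"))

setValidity("OffsetSchedule", function(object) {
  e <- object@entries
  msgs <- character()
  need <- c("index", "offset_ppm", "is_reference")
  if (!all(need %in% names(e)))
    return(sprintf("entries must have columns %s", paste(need, collapse = ", ")))
  if (nrow(e) < 5L)
    msgs <- c(msgs, "schedule must contain at least 5 dynamics")
  if (!identical(as.integer(sort(e$index)), seq_len(nrow(e)) - 1L))
    msgs <- c(msgs, "dynamic indices must be unique and contiguous from 0")
  if (sum(e$is_reference) < 2L)
    msgs <- c(msgs, "schedule needs at least 2 reference dynamics")
  sat <- e[!e$is_reference, , drop = FALSE]
  if (nrow(sat) < 3L)
    msgs <- c(msgs, "schedule needs at least 3 saturated offsets")
  if (any(!is.finite(sat$offset_ppm)))
    msgs <- c(msgs, "saturated offsets must be finite")
  if (length(msgs)) msgs else TRUE
})

# ---------------------------------------------------------------------------
# ZSpectrumStack
# ---------------------------------------------------------------------------

#' Per-voxel normalized z-spectra on a common offset grid
#'
#' Holds Z(Δω) = S(Δω)/S0 for every voxel of a 2D slice, sorted by offset.
#' Rows of `values` are voxels in column-major image order; voxels outside
#' `mask` carry `NA`.
#'
#' @slot values numeric matrix, `prod(dims)` rows by `length(offsets)`
#'   columns.
#' @slot offsets strictly increasing numeric vector of offsets (ppm).
#' @slot mask logical matrix of the slice geometry; `TRUE` where spectra are
#'   valid.
#' @slot dims integer in-plane dimensions.
#' @slot provenance list recording the schedule, the drift model and any
#'   processing applied (B0 recentring, MT subtraction).
#'
#' @export
setClass("ZSpectrumStack", representation(
  values = "matrix", offsets = "numeric", mask = "matrix",
  dims = "integer", provenance = "list"))

setValidity("ZSpectrumStack", function(object) {
  msgs <- character()
  if (length(object@dims) != 2L || any(object@dims < 1L))
    msgs <- c(msgs, "dims must be two positive integers")
  if (nrow(object@values) != prod(object@dims))
    msgs <- c(msgs, "values must have one row per voxel")
  if (ncol(object@values) != length(object@offsets))
    msgs <- c(msgs, "values must have one column per offset")
  if (length(object@offsets) > 1L && any(diff(object@offsets) <= 0))
    msgs <- c(msgs, "offsets must be strictly increasing")
  if (!identical(dim(object@mask), object@dims))
    msgs <- c(msgs, "mask geometry must match dims")
  if (length(msgs)) msgs else TRUE
})

# ---------------------------------------------------------------------------
# Phantom ground truth
# ---------------------------------------------------------------------------

#' Lorentzian pool specification
#'
#' One saturation pool of the z-spectrum model: a Lorentzian line with
#' amplitude (fraction of Z), full width at half maximum (ppm), and chemical
#' shift (ppm from water).
#'
#' @slot name pool label, e.g. `"DS"`, `"MT"`, `"amine"`, `"rNOE"`.
#' @slot amplitude peak amplitude, dimensionless fraction in \[0, 1\].
#' @slot width FWHM in ppm, > 0.
#' @slot center chemical shift in ppm.
#' @export
setClass("PoolSpec", representation(
  name = "character", amplitude = "numeric", width = "numeric",
  center = "numeric"))

setValidity("PoolSpec", function(object) {
  msgs <- character()
  if (length(object@amplitude) != 1L || object@amplitude < 0)
    msgs <- c(msgs, "amplitude must be a single value >= 0")
  if (length(object@width) != 1L || !is.finite(object@width) ||
      object@width <= 0)
    msgs <- c(msgs, "width must be a single positive value")
  if (length(object@center) != 1L || !is.finite(object@center))
    msgs <- c(msgs, "center must be a single finite value")
  if (length(msgs)) msgs else TRUE
})

#' Tissue class with pool parameters and relaxation rate
#'
#' @slot label tissue label (`GM`, `WM`, `CSF`, `WM_lesion`,
#'   `cortical_lesion`, `background`).
#' @slot pools list of [PoolSpec-class] objects (empty for background).
#' @slot zBase baseline saturation level (1 with perfect saturation
#'   efficiency).
#' @slot r1 longitudinal relaxation rate, 1/s (`NA` for background).
#' @export
setClass("TissueClass", representation(
  label = "character", pools = "list", zBase = "numeric", r1 = "numeric"))

setValidity("TissueClass", function(object) {
  msgs <- character()
  if (!all(vapply(object@pools, is, logical(1), class2 = "PoolSpec")))
    msgs <- c(msgs, "pools must all be PoolSpec objects")
  if (object@zBase > 1 + 1e-9 || object@zBase <= 0)
    msgs <- c(msgs, "zBase must be in (0, 1]")
  amps <- vapply(object@pools, function(p) p@amplitude, numeric(1))
  if (length(amps) && sum(amps) >= object@zBase)
    msgs <- c(msgs, sprintf(
      "class '%s': pool amplitudes sum to %.3f >= zBase %.3f (simulated Z would reach 0)",
      object@label, sum(amps), object@zBase))
  if (object@label != "background" &&
      (!is.finite(object@r1) || object@r1 <= 0))
    msgs <- c(msgs, sprintf("class '%s': r1 must be > 0", object@label))
  if (length(msgs)) msgs else TRUE
})

#' Ground truth for a synthetic phantom
#'
#' Complete per-voxel description of a simulated slice: tissue labels, pool
#' parameters, B0/B1 fields, signal drift and noise settings. All simulators
#' and every downstream validation read the truth from this object.
#'
#' @slot labelMap integer matrix of indices into `tissues` (0 = background).
#' @slot tissues named list of [TissueClass-class] objects, in label-index
#'   order.
#' @slot b0Field numeric matrix, voxel-wise B0 offset in ppm.
#' @slot b1Field numeric matrix, voxel-wise relative transmit scale.
#' @slot drift list describing the multiplicative S0 drift over dynamics
#'   (`type` = `"constant"` or `"linear"`, plus parameters).
#' @slot noiseSd additive noise SD as a fraction of the unsaturated signal.
#' @slot noiseModel `"gaussian"` (default) or `"rician"`.
#' @slot seed integer seed recorded at construction.
#' @export
setClass("PhantomTruth", representation(
  labelMap = "matrix", tissues = "list", b0Field = "matrix",
  b1Field = "matrix", drift = "list", noiseSd = "numeric",
  noiseModel = "character", seed = "integer"))

setValidity("PhantomTruth", function(object) {
  msgs <- character()
  d <- dim(object@labelMap)
  if (any(d < 8L))
    msgs <- c(msgs, "grid size must be at least 8x8")
  if (!identical(dim(object@b0Field), d) || !identical(dim(object@b1Field), d))
    msgs <- c(msgs, "b0Field/b1Field geometry must match labelMap")
  if (any(abs(object@b0Field) > 0.5 + 1e-12))
    msgs <- c(msgs, "b0Field must stay within +/-0.5 ppm")
  if (any(object@b1Field <= 0))
    msgs <- c(msgs, "b1Field must be positive")
  if (object@noiseSd < 0)
    msgs <- c(msgs, "noiseSd must be >= 0")
  if (!object@noiseModel %in% c("gaussian", "rician"))
    msgs <- c(msgs, "noiseModel must be 'gaussian' or 'rician'")
  lm <- object@labelMap
  if (any(lm < 0L) || any(lm > length(object@tissues)))
    msgs <- c(msgs, "labelMap indices out of range of tissues")
  if (length(msgs)) msgs else TRUE
})

# ---------------------------------------------------------------------------
# Fit results and maps
# ---------------------------------------------------------------------------

#' Per-voxel two-pool Lorentzian fit results
#'
#' @slot params numeric matrix with one row per voxel and columns `zBase`,
#'   `dsA`, `dsW`, `mtA`, `mtW`, `residRms`.
#' @slot converged logical per voxel.
#' @slot atBound logical per voxel (any parameter within 1e-6 of a bound).
#' @slot mask logical matrix of fitted voxels.
#' @slot dims integer slice dimensions.
#' @slot bounds the [FitBounds-class] used.
#' @export
setClass("TwoPoolFitSet", representation(
  params = "matrix", converged = "logical", atBound = "logical",
  mask = "matrix", dims = "integer", bounds = "ANY"))

#' Bounds and initial guesses for the two-pool Lorentzian fit
#'
#' Amplitudes are fractions of Z (percent values divided by 100), widths are
#' FWHM in ppm. Rows: `lower`, `upper`, `init`; columns: `dsA`, `mtA`,
#' `dsW`, `mtW`.
#'
#' @slot table numeric 3 x 4 matrix.
#' @seealso [defaultFitBounds()]
#' @export
setClass("FitBounds", representation(table = "matrix"))

setValidity("FitBounds", function(object) {
  tb <- object@table
  if (!identical(rownames(tb), c("lower", "upper", "init")))
    return("rows must be lower, upper, init")
  if (!identical(colnames(tb), c("dsA", "mtA", "dsW", "mtW")))
    return("columns must be dsA, mtA, dsW, mtW")
  if (any(tb["lower", ] > tb["init", ] | tb["init", ] > tb["upper", ]))
    return("must satisfy lower <= init <= upper for every parameter")
  TRUE
})

#' Voxel-wise B0 shift map from WASSR
#'
#' @slot shift numeric matrix, water frequency shift in ppm.
#' @slot fitQuality numeric matrix, RMS symmetry residual at the optimum.
#' @slot mask logical matrix of valid voxels.
#' @slot flat logical matrix; `TRUE` where the spectrum had no usable water
#'   dip and the shift was set to 0.
#' @export
setClass("B0Map", representation(
  shift = "matrix", fitQuality = "matrix", mask = "matrix", flat = "matrix"))

setValidity("B0Map", function(object) {
  if (any(!is.finite(object@shift[object@mask])))
    return("shift must be finite within mask")
  TRUE
})

#' Relative transmit (B1) map from dual-TR AFI
#'
#' @slot relativeFlip numeric matrix, actual/nominal flip angle.
#' @slot mask logical matrix; voxels where the AFI ratio was invertible and
#'   the relative flip lies in (0, 2).
#' @export
setClass("B1Map", representation(relativeFlip = "matrix", mask = "matrix"))

setValidity("B1Map", function(object) {
  v <- object@relativeFlip[object@mask]
  if (any(!is.finite(v)) || any(v <= 0) || any(v >= 2))
    return("relativeFlip must lie in (0, 2) within mask")
  TRUE
})

#' Voxel-wise longitudinal relaxation map
#'
#' @slot r1 numeric matrix, 1/s.
#' @slot m0 numeric matrix, equilibrium signal (arbitrary units).
#' @slot invEfficiency numeric matrix, inversion efficiency in \[0, 2\]
#'   (2 - flip fraction; 1 is a perfect inversion in the
#'   `1 - (1 + e) exp(-TI R1)` parameterization).
#' @slot residRms numeric matrix.
#' @slot mask logical matrix of successfully fitted voxels.
#' @export
setClass("R1Map", representation(
  r1 = "matrix", m0 = "matrix", invEfficiency = "matrix",
  residRms = "matrix", mask = "matrix"))

setValidity("R1Map", function(object) {
  v <- object@r1[object@mask]
  if (any(!is.finite(v)) || any(v <= 0))
    return("r1 must be finite and > 0 within mask")
  TRUE
})

#' CEST contrast maps at a target offset
#'
#' @slot mtrAsymCorr numeric matrix, MT-corrected MTR asymmetry (fraction).
#' @slot mtrRexCorr numeric matrix, MT/spillover-corrected inverse
#'   difference (dimensionless).
#' @slot arexCorr numeric matrix, T1-corrected exchange contrast (1/s).
#' @slot legacyGlucest numeric matrix, uncorrected asymmetry contrast
#'   (percent).
#' @slot targetOffset target offset in ppm (3.0 for amine protons).
#' @slot variant `"z_space_subtraction"` or `"inverse_space_subtraction"`.
#' @slot mask logical matrix of voxels valid in all maps.
#' @export
setClass("ContrastMaps", representation(
  mtrAsymCorr = "matrix", mtrRexCorr = "matrix", arexCorr = "matrix",
  legacyGlucest = "matrix", targetOffset = "numeric", variant = "character",
  mask = "matrix"))

setValidity("ContrastMaps", function(object) {
  if (!object@variant %in% c("z_space_subtraction", "inverse_space_subtraction"))
    return("unknown variant")
  TRUE
})
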