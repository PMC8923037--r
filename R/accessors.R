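# Generics, accessors and show methods for the core containers.

#' @rdname OffsetSchedule-class
#' @param entries data.frame with columns `index`, `offset_ppm`,
#'   `is_reference`
#' @return an `OffsetSchedule`
#' @export
offsetSchedule <- function(entries) {
  entries$index <- as.integer(entries$index)
  entries$offset_ppm <- as.numeric(entries$offset_ppm)
  entries$is_reference <- as.logical(entries$is_reference)
  new("OffsetSchedule", entries = entries[order(entries$index), ])
}

#' Schedule accessors
#'
#' `scheduleOffsets` returns the saturated offsets in acquisition order;
#' `referenceIndices`/`saturatedIndices` return 0-based acquisition indices;
#' `nDynamics` the total number of dynamics.
#'
#' @param x an [OffsetSchedule-class]
#' @return numeric or integer vectors
#' @export
scheduleOffsets <- function(x) {
  e <- x@entries
  e$offset_ppm[!e$is_reference]
}

#' @rdname scheduleOffsets
#' @export
referenceIndices <- function(x) x@entries$index[x@entries$is_reference]

#' @rdname scheduleOffsets
#' @export
saturatedIndices <- function(x) x@entries$index[!x@entries$is_reference]

#' @rdname scheduleOffsets
#' @export
nDynamics <- function(x) nrow(x@entries)

setMethod("show", "OffsetSchedule", function(object) {
  e <- object@entries
  sat <- e$offset_ppm[!e$is_reference]
  cat(sprintf("OffsetSchedule: %d dynamics (%d saturated, %d references)\n",
              nrow(e), sum(!e$is_reference), sum(e$is_reference)))
  cat(sprintf("  offsets: %.1f to %.1f ppm\n", min(sat), max(sat)))
})

#' Z-spectrum stack accessors
#'
#' @param x a [ZSpectrumStack-class]
#' @return `zValues`: voxel-by-offset matrix; `zOffsets`: ppm vector;
#'   `zMask`: logical matrix; `imgDim`: slice dimensions.
#' @export
zValues <- function(x) x@values

#' @rdname zValues
#' @export
zOffsets <- function(x) x@offsets

#' @rdname zValues
#' @export
zMask <- function(x) x@mask

#' @rdname zValues
#' @export
imgDim <- function(x) x@dims

setMethod("show", "ZSpectrumStack", function(object) {
  cat(sprintf("ZSpectrumStack: %dx%d slice, %d offsets (%.1f..%.1f ppm), %d masked voxels\n",
              object@dims[1], object@dims[2], length(object@offsets),
              min(object@offsets), max(object@offsets), sum(object@mask)))
  if (length(object@provenance))
    cat("  provenance:", paste(names(object@provenance), collapse = ", "), "\n")
})

#' Construct a Lorentzian pool
#'
#' @param name pool label
#' @param amplitude peak amplitude (fraction of Z)
#' @param width FWHM, ppm
#' @param center chemical shift, ppm
#' @return a [PoolSpec-class]
#' @export
poolSpec <- function(name, amplitude, width, center)
  new("PoolSpec", name = name, amplitude = amplitude, width = width,
      center = center)

#' Construct a tissue class
#'
#' @param label tissue label
#' @param pools list of [PoolSpec-class]
#' @param zBase baseline saturation (default 1)
#' @param r1 longitudinal relaxation rate, 1/s
#' @return a [TissueClass-class]
#' @export
tissueClass <- function(label, pools = list(), zBase = 1.0, r1 = NA_real_)
  new("TissueClass", label = label, pools = pools, zBase = zBase, r1 = r1)

setMethod("show", "PhantomTruth", function(object) {
  d <- dim(object@labelMap)
  cat(sprintf("PhantomTruth: %dx%d grid, %d tissue classes, noiseSd=%.4g (%s), seed=%d\n",
              d[1], d[2], length(object@tissues), object@noiseSd,
              object@noiseModel, object@seed))
  tab <- table(factor(object@labelMap, levels = 0:length(object@tissues),
                      labels = c("background",
                                 vapply(object@tissues, function(t) t@label,
                                        character(1)))))
  print(tab)
})

#' Phantom accessors
#'
#' @param x a [PhantomTruth-class]
#' @return `labelMap`: integer matrix; `tissueClasses`: named list;
#'   `b0Field`/`b1Field`: matrices; `tissueMask`: logical matrix for one
#'   label.
#' @export
labelMap <- function(x) x@labelMap

#' @rdname labelMap
#' @export
tissueClasses <- function(x) x@tissues

#' @rdname labelMap
#' @export
b0Field <- function(x) x@b0Field

#' @rdname labelMap
#' @export
b1Field <- function(x) x@b1Field

#' @rdname labelMap
#' @param label a tissue label present in `tissueClasses(x)`
#' @export
tissueMask <- function(x, label) {
  labs <- vapply(x@tissues, function(t) t@label, character(1))
  idx <- match(label, labs)
  if (is.na(idx)) stop("unknown tissue label: ", label)
  x@labelMap == idx
}

setMethod("show", "TwoPoolFitSet", function(object) {
  cat(sprintf("TwoPoolFitSet: %d fitted voxels (%d converged, %d at bound)\n",
              sum(object@mask), sum(object@converged, na.rm = TRUE),
              sum(object@atBound, na.rm = TRUE)))
  cat(sprintf("  median residual RMS: %.3g\n",
              median(object@params[object@mask, "residRms"], na.rm = TRUE)))
})

#' Fit-set accessors
#'
#' @param x a [TwoPoolFitSet-class]
#' @return `fitParams`: voxel-by-parameter matrix; `fitMask`: logical
#'   matrix; `fitConverged`/`fitAtBound`: logical vectors.
#' @export
fitParams <- function(x) x@params

#' @rdname fitParams
#' @export
fitMask <- function(x) x@mask

#' @rdname fitParams
#' @export
fitConverged <- function(x) x@converged

#' @rdname fitParams
#' @export
fitAtBound <- function(x) x@atBound

setMethod("show", "B0Map", function(object) {
  v <- object@shift[object@mask]
  cat(sprintf("B0Map: %d voxels, shift %.3f..%.3f ppm (median %.3f), %d flat\n",
              sum(object@mask), min(v), max(v), median(v), sum(object@flat)))
})

setMethod("show", "B1Map", function(object) {
  v <- object@relativeFlip[object@mask]
  cat(sprintf("B1Map: %d valid voxels, relative flip %.3f..%.3f\n",
              sum(object@mask), min(v), max(v)))
})

setMethod("show", "R1Map", function(object) {
  v <- object@r1[object@mask]
  cat(sprintf("R1Map: %d voxels, R1 %.3f..%.3f 1/s (median %.3f)\n",
              sum(object@mask), min(v), max(v), median(v)))
})

#' Map accessors
#'
#' @param x a map object (`B0Map`, `B1Map`, `R1Map`)
#' @return the underlying numeric matrix / logical mask
#' @export
b0Shift <- function(x) x@shift

#' @rdname b0Shift
#' @export
relativeFlip <- function(x) x@relativeFlip

#' @rdname b0Shift
#' @export
r1Values <- function(x) x@r1

#' @rdname b0Shift
#' @export
mapMask <- function(x) x@mask

setMethod("show", "ContrastMaps", function(object) {
  m <- object@mask
  cat(sprintf("ContrastMaps at %+.1f ppm (%s): %d valid voxels\n",
              object@targetOffset, object@variant, sum(m)))
  for (nm in c("mtrAsymCorr", "mtrRexCorr", "arexCorr", "legacyGlucest")) {
    v <- slot(object, nm)[m]
    cat(sprintf("  %-13s median %.4g\n", nm, median(v, na.rm = TRUE)))
  }
})

#' Contrast-map accessors
#'
#' @param x a [ContrastMaps-class]
#' @return the requested map as a matrix of the slice geometry
#' @export
mtrAsymCorr <- function(x) x@mtrAsymCorr

#' @rdname mtrAsymCorr
#' @export
mtrRexCorr <- function(x) x@mtrRexCorr

#' @rdname mtrAsymCorr
#' @export
arexCorr <- function(x) x@arexCorr

#' @rdname mtrAsymCorr
#' @export
legacyGlucestMap <- function(x) x@legacyGlucest
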