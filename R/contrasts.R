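# CEST contrast maps at a target offset: legacy asymmetry, MT-corrected
# asymmetry, spillover-corrected inverse difference, and T1-corrected AREX.

#' Legacy asymmetry contrast (uncorrected)
#'
#' `100 * (Z(-target) - Z(+target)) / Z(-target)` in percent, the
#' conventional glutamate-weighted CEST asymmetry. Voxels with
#' `Z(-target) <= 0` are invalid.
#'
#' @param zstack a [ZSpectrumStack-class] (B0-recentred, uncorrected)
#' @param target target offset in ppm (default 3.0, amine protons)
#' @return numeric matrix of the slice geometry, percent
#' @export
legacyGlucest <- function(zstack, target = 3.0) {
  zm <- sampleAtOffset(zstack@values, zstack@offsets, -target)
  zp <- sampleAtOffset(zstack@values, zstack@offsets, target)
  out <- 100 * (zm - zp) / zm
  out[!is.finite(out) | zm <= 0] <- NA_real_
  matrix(out, zstack@dims[1], zstack@dims[2])
}

#' MT-corrected MTR asymmetry
#'
#' `Z_corr(-target) - Z_corr(+target)` on MT-subtracted spectra.
#'
#' @param zcorr an MT-corrected [ZSpectrumStack-class] (see [subtractMt()])
#' @param target target offset, ppm
#' @return numeric matrix (fraction)
#' @export
computeMtrAsymCorr <- function(zcorr, target = 3.0) {
  zm <- sampleAtOffset(zcorr@values, zcorr@offsets, -target)
  zp <- sampleAtOffset(zcorr@values, zcorr@offsets, target)
  matrix(zm - zp, zcorr@dims[1], zcorr@dims[2])
}

#' MT- and spillover-corrected inverse difference
#'
#' Default variant (`"z_space_subtraction"`): the MT baseline is removed in
#' Z-space (see [subtractMt()]) and the corrected spectrum inverted,
#' `1/Z_corr(+target) - 1/Z_corr(-target)`. The alternative
#' (`"inverse_space_subtraction"`) corrects in inverse space,
#' `1/Z_corr = 1/Z - 1/Z_refMT` with `Z_refMT = zBase - L_MT` (the fitted
#' MT-only spectrum), before differencing; the two forms are not
#' algebraically equivalent and the variant is recorded on the result.
#' Voxels with a non-positive corrected spectrum at either side are
#' invalid; counts are attached as attribute `"invalid"`.
#'
#' @param zstack the measured (uncorrected, recentred)
#'   [ZSpectrumStack-class]
#' @param fits the [TwoPoolFitSet-class] for the same stack
#' @param target target offset, ppm
#' @param variant `"z_space_subtraction"` (default) or
#'   `"inverse_space_subtraction"`
#' @return numeric matrix (dimensionless)
#' @export
computeMtrRexCorr <- function(zstack, fits, target = 3.0,
                              variant = c("z_space_subtraction",
                                          "inverse_space_subtraction")) {
  variant <- match.arg(variant)
  off <- zstack@offsets
  mask <- as.vector(zstack@mask & fits@mask)
  nVox <- prod(zstack@dims)
  mtP <- vapply(seq_len(nVox), function(i)
    if (mask[i]) mtBaseline(fits@params[i, ], target) else NA_real_,
    numeric(1))
  mtM <- vapply(seq_len(nVox), function(i)
    if (mask[i]) mtBaseline(fits@params[i, ], -target) else NA_real_,
    numeric(1))
  zp <- sampleAtOffset(zstack@values, off, target)
  zm <- sampleAtOffset(zstack@values, off, -target)
  if (variant == "z_space_subtraction") {
    zcp <- zp + mtP
    zcm <- zm + mtM
    bad <- mask & (is.na(zcp) | is.na(zcm) | zcp <= 0 | zcm <= 0)
    out <- 1 / zcp - 1 / zcm
  } else {
    # inverse-space form: 1/Zcorr = 1/Z - 1/Z_refMT with Z_refMT the fitted
    # MT-only spectrum (zBase - L_MT), then difference across +/-target
    zb <- fits@params[, "zBase"]
    refP <- zb - mtP
    refM <- zb - mtM
    bad <- mask & (is.na(zp) | is.na(zm) | zp <= 0 | zm <= 0 |
                     refP <= 0 | refM <= 0)
    out <- (1 / zp - 1 / refP) - (1 / zm - 1 / refM)
  }
  out[!mask | bad] <- NA_real_
  res <- matrix(out, zstack@dims[1], zstack@dims[2])
  attr(res, "invalid") <- sum(bad)
  attr(res, "variant") <- variant
  res
}

#' T1-corrected exchange contrast (AREX)
#'
#' Elementwise product of the spillover-corrected inverse difference and
#' the longitudinal relaxation rate: `AREX = MTR_RexCorr * R1`, in 1/s.
#'
#' @param mtrRexMap numeric matrix from [computeMtrRexCorr()]
#' @param r1 an [R1Map-class] or a numeric matrix of R1 values (1/s)
#' @return numeric matrix, 1/s
#' @export
computeArexCorr <- function(mtrRexMap, r1) {
  r1m <- if (is(r1, "R1Map")) {
    v <- r1@r1; v[!r1@mask] <- NA_real_; v
  } else r1
  if (!identical(dim(r1m), dim(mtrRexMap)))
    stop("R1 map geometry does not match the contrast map")
  r1m[!is.na(r1m) & r1m <= 0] <- NA_real_
  mtrRexMap * r1m
}

#' Compute all contrast maps at a target offset
#'
#' Convenience wrapper producing the legacy asymmetry, corrected MTR
#' asymmetry, corrected inverse difference and AREX on one mask.
#'
#' @param zstack measured (recentred) [ZSpectrumStack-class]
#' @param fits matching [TwoPoolFitSet-class]
#' @param r1 an [R1Map-class] or numeric matrix
#' @param target target offset, ppm
#' @param variant see [computeMtrRexCorr()]
#' @return a [ContrastMaps-class]
#' @export
computeContrastMaps <- function(zstack, fits, r1, target = 3.0,
                                variant = "z_space_subtraction") {
  zcorr <- subtractMt(zstack, fits)
  asym <- computeMtrAsymCorr(zcorr, target)
  rex <- computeMtrRexCorr(zstack, fits, target, variant)
  arex <- computeArexCorr(rex, r1)
  leg <- legacyGlucest(zstack, target)
  mask <- zcorr@mask & is.finite(asym) & is.finite(rex) & is.finite(arex)
  new("ContrastMaps", mtrAsymCorr = asym, mtrRexCorr = rex, arexCorr = arex,
      legacyGlucest = leg, targetOffset = target, variant = variant,
      mask = mask)
}
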