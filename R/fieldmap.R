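# B0 mapping from WASSR, spectrum recentring, and dual-TR AFI B1 mapping.

# Symmetry cost of a spectrum spline about candidate centers delta:
# mean_x (f(delta + x) - f(delta - x))^2 over a fixed positive lag grid.
symmetryCost <- function(fun, deltas, lags) {
  vapply(deltas, function(d)
    mean((fun(d + lags) - fun(d - lags))^2), numeric(1))
}

#' Fit the voxel-wise B0 shift map from a WASSR series
#'
#' Maximum-symmetry center estimation: for each voxel, the water shift is
#' the center `delta` minimizing the mean squared difference between the
#' cubic-spline-interpolated spectrum and its mirror about `delta`. The
#' search runs a coarse grid, then a fine grid at `fineStep` around the
#' coarse optimum, then continuous refinement with [stats::optimize] — pure
#' enumeration plus a bracketed 1D minimization, robust for the single-dip
#' WASSR line shape.
#'
#' Voxels whose spectrum has no usable water dip (range below `flatTol`)
#' are flagged and assigned shift 0.
#'
#' @param zstack WASSR spectra assembled by [driftCorrectNormalize()]
#' @param searchBound maximum |shift| searched, ppm (default 0.5)
#' @param coarseStep,fineStep grid resolutions in ppm
#' @param flatTol minimum spectrum range for a usable dip
#' @return a [B0Map-class]
#' @export
fitWassrB0 <- function(zstack, searchBound = 0.5, coarseStep = 0.01,
                       fineStep = 0.001, flatTol = 0.02) {
  off <- zstack@offsets
  if (length(off) < 9L) stop("WASSR needs at least 9 offsets")
  if (abs(max(off) + min(off)) > 0.2)
    stop("WASSR schedule must be (approximately) symmetric about 0")
  bound <- min(searchBound, max(off) - 0.5)  # keep delta +/- lag in range
  if (bound <= 0) stop("searchBound leaves no room inside the offset grid")
  lagMax <- max(off) - bound
  lags <- seq(0.05, lagMax, by = 0.05)
  coarse <- seq(-bound, bound, by = coarseStep)

  d <- zstack@dims
  shift <- matrix(NA_real_, d[1], d[2])
  quality <- matrix(NA_real_, d[1], d[2])
  flat <- matrix(FALSE, d[1], d[2])
  vox <- which(as.vector(zstack@mask))
  for (i in vox) {
    z <- zstack@values[i, ]
    if (diff(range(z)) < flatTol) {
      shift[i] <- 0; quality[i] <- NA_real_; flat[i] <- TRUE
      next
    }
    f <- splinefun(off, z, method = "fmm")
    cc <- symmetryCost(f, coarse, lags)
    best <- coarse[which.min(cc)]
    fine <- seq(max(-bound, best - coarseStep),
                min(bound, best + coarseStep), by = fineStep)
    fc <- symmetryCost(f, fine, lags)
    best <- fine[which.min(fc)]
    opt <- optimize(function(x) symmetryCost(f, x, lags),
                    c(max(-bound, best - fineStep),
                      min(bound, best + fineStep)))
    shift[i] <- opt$minimum
    quality[i] <- sqrt(opt$objective)
  }
  new("B0Map", shift = shift, fitQuality = quality, mask = zstack@mask,
      flat = flat)
}

#' Recenter z-spectra at 0 ppm using a B0 map
#'
#' Each voxel's spectrum is resampled by cubic spline at `offset + shift`
#' so the water resonance sits at 0 ppm; the offset grid itself is
#' unchanged, keeping all voxels on one common grid. Edge offsets whose
#' shifted sampling point falls outside the measured range are set `NA` and
#' counted in the provenance. Voxels with zero shift are copied bitwise.
#'
#' @param zstack a [ZSpectrumStack-class]
#' @param b0 a [B0Map-class] with the same geometry
#' @return a recentred [ZSpectrumStack-class]
#' @export
recenterSpectra <- function(zstack, b0) {
  if (!identical(dim(b0@shift), zstack@dims))
    stop("B0 map geometry does not match the spectrum stack")
  off <- zstack@offsets
  out <- zstack@values
  nEdge <- 0L
  for (i in which(as.vector(zstack@mask))) {
    s <- b0@shift[i]
    if (is.na(s) || s == 0) next
    x <- off + s
    inside <- x >= off[1] & x <= off[length(off)]
    nEdge <- nEdge + sum(!inside)
    v <- rep(NA_real_, length(off))
    v[inside] <- splinefun(off, zstack@values[i, ], method = "fmm")(x[inside])
    out[i, ] <- v
  }
  prov <- zstack@provenance
  prov$b0_recentred <- TRUE
  prov$n_edge_invalid <- nEdge
  new("ZSpectrumStack", values = out, offsets = off, mask = zstack@mask,
      dims = zstack@dims, provenance = prov)
}

#' Compute the relative transmit (B1) map from a dual-TR AFI pair
#'
#' With `n = TR2/TR1` and ratio `r = S2/S1`, the actual flip angle is
#' `acos((r n - 1)/(n - r))`; the map reports `actual/nominal`. Ratios
#' outside the invertible domain `(1/n, 1]` are flagged invalid; small
#' noise overshoots `r` in `(1, 1 + rTol]` are clipped to 1.
#'
#' @param s1,s2 matrices, the two AFI steady-state images
#' @param tr1,tr2 repetition times (ms), `tr2 > tr1`
#' @param nominalFlip nominal flip angle, degrees
#' @param mask optional logical matrix of voxels to invert
#' @param rTol clipping tolerance above 1 for the signal ratio
#' @return a [B1Map-class]
#' @export
computeAfiB1 <- function(s1, s2, tr1 = 35, tr2 = 160, nominalFlip = 60,
                         mask = NULL, rTol = 0.02) {
  if (tr2 <= tr1) stop("need TR2 > TR1")
  if (is.null(mask)) mask <- s1 > 0 & s2 > 0
  n <- tr2 / tr1
  r <- s2 / s1
  r[r > 1 & r <= 1 + rTol] <- 1
  invertible <- mask & is.finite(r) & r > 1 / n & r <= 1
  cosA <- (r * n - 1) / (n - r)
  cosA[cosA > 1] <- 1
  cosA[cosA < -1] <- -1
  alpha <- acos(cosA) * 180 / pi
  rel <- alpha / nominalFlip
  valid <- invertible & rel > 0 & rel < 2
  rel[!valid] <- NA_real_
  new("B1Map", relativeFlip = rel, mask = valid)
}
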