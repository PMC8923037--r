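# Shared fixtures: small noiseless phantoms and independent forward models.

# Phantom with all amine amplitudes replaced (NULL keeps defaults).
fixturePhantom <- function(gridSize = 16, noiseSd = 0, amine = NULL,
                           b0 = list(mode = "constant", value = 0),
                           drift = list(type = "constant", value = 1),
                           seed = 1L, ...) {
  tt <- defaultTissueTable(...)
  if (!is.null(amine))
    tt <- lapply(tt, function(tc) arexcest:::setAmineAmplitude(tc, amine))
  buildPhantom(tt, gridSize = gridSize, b0 = b0, drift = drift,
               noiseSd = noiseSd, seed = seed)
}

# Independent Lorentzian forward model (written from the line-shape
# definition, not via the package).
refLorentz <- function(A, sigma, center, w) A / (1 + 4 * ((w - center) / sigma)^2)

refTwoPool <- function(dsA, dsW, mtA, mtW, w, zBase = 1)
  zBase - refLorentz(dsA, dsW, 0, w) - refLorentz(mtA, mtW, -2.4, w)

# Assemble a ZSpectrumStack directly from given spectra (bypasses the
# drift-correction path; for unit tests of downstream stages).
stackFromValues <- function(values, offsets, dims = NULL) {
  if (is.null(dims)) dims <- c(nrow(values), 1L)
  mask <- matrix(rowSums(is.finite(values)) > 0, dims[1], dims[2])
  new("ZSpectrumStack", values = values, offsets = offsets, mask = mask,
      dims = as.integer(dims), provenance = list())
}

# Exhaustive grid-search oracle for the two-pool model: enumerates the
# full bound box at amplitude step 0.005 and width step 0.25 ppm. For a
# fixed width pair the SSQ is a convex quadratic in the amplitudes, so the
# exact grid minimum over the DS amplitude is one of the two grid
# neighbors of the analytic minimizer; the MT amplitude grid is swept
# explicitly. No gradient steps anywhere.
gridOracleTwoPool <- function(z, off, zBase = 1) {
  r <- z - zBase
  dsWs <- seq(0.1, 5, by = 0.25)
  mtWs <- seq(10, 100, by = 0.25)
  Bs <- seq(0, 0.90, by = 0.005)
  K1 <- vapply(dsWs, function(s) refLorentz(1, s, 0, off),
               numeric(length(off)))
  K2 <- vapply(mtWs, function(s) refLorentz(1, s, -2.4, off),
               numeric(length(off)))
  a1 <- drop(crossprod(K1, r)); a2 <- drop(crossprod(K2, r))
  b1 <- colSums(K1^2); b2 <- colSums(K2^2)
  X <- crossprod(K1, K2)
  r2 <- sum(r^2)
  snapA <- function(a) pmin(1, pmax(0.20, round(a / 0.005) * 0.005))
  best <- list(s = Inf)
  for (i in seq_along(dsWs)) for (j in seq_along(mtWs)) {
    aStar <- -(a1[i] + Bs * X[i, j]) / b1[i]
    cand <- rbind(snapA(aStar - 0.0025), snapA(aStar + 0.0025))
    S <- r2 + 2 * cand * a1[i] + 2 * rep(Bs, each = 2) * a2[j] +
      cand^2 * b1[i] + rep(Bs^2, each = 2) * b2[j] +
      2 * cand * rep(Bs, each = 2) * X[i, j]
    k <- which.min(S)
    if (S[k] < best$s) {
      bi <- (k + 1) %/% 2
      best <- list(s = S[k], p = c(dsA = cand[k], mtA = Bs[bi],
                                   dsW = dsWs[i], mtW = mtWs[j]))
    }
  }
  best$p
}

r1TruthByClass <- function(phantom)
  c(NA_real_, vapply(tissueClasses(phantom), function(t) t@r1, numeric(1)))
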