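# Inversion-recovery R1 mapping with magnitude polarity restoration, and
# the thin-slice collapsing rules for maps and masks.

# Signed IR model: m0 * (1 - (1 + e) * exp(-ti_s * r1)), ti in seconds.
irModel <- function(p, tiS) p[1] * (1 - (1 + p[2]) * exp(-tiS * p[3]))

fitIrVoxel <- function(sig, tiS) {
  if (diff(range(sig)) < 1e-9 * max(abs(sig), 1)) return(NULL)  # flat
  jmin <- which.min(sig)
  flips <- unique(pmax(0L, pmin(length(sig), c(jmin - 1L, jmin, jmin + 1L))))
  m0Init <- max(sig)
  best <- NULL
  for (k in flips) {
    s <- sig * c(rep(-1, k), rep(1, length(sig) - k))
    tiNull <- if (k >= 1) tiS[min(k + 1L, length(sig))] else tiS[2]
    start <- c(m0 = m0Init, e = 1, r1 = max(min(log(2) / tiNull, 15), 0.2))
    fit <- tryCatch(minpack.lm::nls.lm(
      par = start, lower = c(1e-9, 0, 0.01), upper = c(Inf, 2, 50),
      fn = function(p) s - irModel(p, tiS),
      control = minpack.lm::nls.lm.control(ftol = 1e-12, ptol = 1e-12,
                                           maxiter = 300)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss)
      best <- list(par = fit$par, rss = rss, converged = fit$info %in% 1:4)
  }
  best
}

#' Fit voxel-wise R1 from a magnitude inversion-recovery series
#'
#' Three-parameter magnitude model `|m0 (1 - (1 + e) exp(-TI R1))|` with
#' polarity restoration: candidate sign-flip points around the signal
#' minimum are tried with a signed bounded Levenberg-Marquardt fit and the
#' best residual wins. `e` is the inversion efficiency (1 = perfect
#' inversion), bounded in \[0, 2\].
#'
#' @param series numeric array `(x, y, TI)` or voxel-by-TI matrix
#' @param tiList inversion times in ms (at least 5, spanning a decade)
#' @param mask optional logical matrix of voxels to fit
#' @return an [R1Map-class]
#' @export
fitIrR1 <- function(series, tiList, mask = NULL) {
  if (length(tiList) < 5L || max(tiList) / min(tiList) < 10)
    stop("need >= 5 inversion times spanning at least one decade")
  if (length(dim(series)) == 3L) {
    d <- dim(series)[1:2]
    sig <- matrix(series, prod(d), dim(series)[3])
  } else {
    sig <- series
    d <- c(nrow(series), 1L)
  }
  if (ncol(sig) != length(tiList))
    stop("series length does not match tiList")
  if (is.null(mask)) mask <- matrix(TRUE, d[1], d[2])
  tiS <- tiList / 1000
  r1 <- m0 <- eff <- resid <- matrix(NA_real_, d[1], d[2])
  ok <- matrix(FALSE, d[1], d[2])
  for (i in which(as.vector(mask))) {
    f <- fitIrVoxel(sig[i, ], tiS)
    if (is.null(f) || !f$converged || f$par[3] <= 0) next
    r1[i] <- f$par[3]; m0[i] <- f$par[1]; eff[i] <- f$par[2]
    resid[i] <- sqrt(f$rss / length(tiS))
    ok[i] <- TRUE
  }
  new("R1Map", r1 = r1, m0 = m0, invEfficiency = eff, residRms = resid,
      mask = ok)
}

#' Average thin-slice maps into one thick-slice map
#'
#' Voxel-wise mean over the valid (finite) slices; voxels invalid in every
#' slice stay invalid.
#'
#' @param stack numeric array `(x, y, slice)`
#' @return numeric matrix
#' @export
collapseSlicesMean <- function(stack) {
  stopifnot(length(dim(stack)) == 3L)
  out <- apply(stack, c(1, 2), function(v) {
    v <- v[is.finite(v)]
    if (!length(v)) NA_real_ else mean(v)
  })
  out
}

#' Collapse thin-slice binary masks into one thick-slice mask
#'
#' A voxel is retained iff it is present in at least `k` of the slices
#' (`k = 2` of 5 for the tissue and WM-lesion masks; `k = 1` for small
#' cortical lesions). If `exclude` is given (e.g. a collapsed lesion mask),
#' those voxels are removed from the result, keeping normal-appearing
#' masks disjoint from lesions.
#'
#' @param stack logical/0-1 array `(x, y, slice)`
#' @param k minimum number of slices, `1 <= k <= n_slices`
#' @param exclude optional logical matrix of voxels to remove afterwards
#' @return logical matrix
#' @export
collapseMasks <- function(stack, k, exclude = NULL) {
  stopifnot(length(dim(stack)) == 3L)
  nS <- dim(stack)[3]
  if (k < 1 || k > nS) stop("k must be in [1, n_slices]")
  count <- apply(stack, c(1, 2), function(v) sum(v != 0, na.rm = TRUE))
  out <- count >= k
  if (!is.null(exclude)) out <- out & !exclude
  out
}
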