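# ROI summaries and the group statistics used on the contrast maps:
# two-sample / paired t-tests, partial Spearman correlation with
# covariates, and Bonferroni thresholds.

#' Summarize a map over a region of interest
#'
#' Mean, median and a histogram over the valid (finite) voxels of `map`
#' inside `mask`. Histogram bins are uniform over the robust
#' 1st-99th-percentile range by default.
#'
#' @param map numeric matrix
#' @param mask logical matrix, same geometry
#' @param label ROI name used in error messages and the output
#' @param bins number of histogram bins
#' @param probs length-2 quantile range for the histogram
#' @return list with `label`, `nVoxels`, `mean`, `median`, `histogram`
#'   (list of `breaks`, `counts`)
#' @export
roiSummary <- function(map, mask, label = "ROI", bins = 64,
                       probs = c(0.01, 0.99)) {
  if (!identical(dim(map), dim(mask)))
    stop("map and mask geometries differ")
  v <- map[mask & is.finite(map)]
  if (!length(v))
    stop("ROI '", label, "' contains no valid voxels")
  rng <- quantile(v, probs, names = FALSE)
  if (diff(rng) <= 0) rng <- rng + c(-0.5, 0.5)
  breaks <- seq(rng[1], rng[2], length.out = bins + 1)
  counts <- tabulate(findInterval(v, breaks, rightmost.closed = TRUE,
                                  all.inside = TRUE), nbins = bins)
  list(label = label, nVoxels = length(v), mean = mean(v),
       median = median(v), histogram = list(breaks = breaks, counts = counts))
}

#' Two-sample or paired t-test
#'
#' Classic pooled-variance two-sample t by default (`pooled = FALSE` gives
#' Welch), or a paired t-test; two-sided p-values.
#'
#' @param x,y numeric samples (equal length when `paired`)
#' @param paired paired test
#' @param pooled pooled-variance (equal variances) for the two-sample test
#' @return list with `t`, `df`, `p`
#' @export
twoSampleT <- function(x, y, paired = FALSE, pooled = TRUE) {
  if (length(x) < 2 || length(y) < 2) stop("need at least 2 values per sample")
  if (paired && length(x) != length(y))
    stop("paired test requires equal lengths")
  if (paired && stats::sd(x - y) == 0)
    stop("paired differences have zero variance")
  tt <- t.test(x, y, paired = paired, var.equal = pooled)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}

#' Partial Spearman correlation with covariates
#'
#' Rank-transforms `x`, `y` and every covariate column (midranks for
#' ties), removes the covariates from the ranked `x` and `y` by linear
#' regression, and correlates the residuals. The two-sided p-value uses the
#' t approximation with `df = n - 2 - n_covariates`. With no covariates
#' this is ordinary Spearman rank correlation.
#'
#' @param x,y numeric vectors
#' @param covariates optional numeric matrix / data.frame, one row per
#'   observation
#' @return list with `rho`, `p`, `n`, `df`
#' @export
spearmanPartial <- function(x, y, covariates = NULL) {
  n <- length(x)
  if (length(y) != n) stop("x and y lengths differ")
  k <- if (is.null(covariates)) 0L else ncol(as.matrix(covariates))
  if (n <= k + 2) stop("need n > n_covariates + 2 observations")
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != n) stop("covariate rows must match x")
    if (anyNA(covariates) || anyNA(x) || anyNA(y))
      stop("missing values are not allowed in used rows")
  } else if (anyNA(x) || anyNA(y)) stop("missing values are not allowed")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("x and y must be non-constant")
  rx <- rank(x); ry <- rank(y)
  if (k > 0) {
    rc <- apply(covariates, 2, rank)
    rx <- resid(lm(rx ~ rc))
    ry <- resid(lm(ry ~ rc))
  }
  rho <- cor(rx, ry)
  df <- n - 2L - k
  tstat <- rho * sqrt(df / max(1 - rho^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df)
  list(rho = rho, p = p, n = n, df = df)
}

#' Bonferroni-adjusted significance level
#'
#' @param alpha family-wise level in (0, 1)
#' @param m number of comparisons, >= 1
#' @return list with `exact` (`alpha/m`) and `rounded` (4 decimals)
#' @examples
#' bonferroniThreshold(0.05, 38)$rounded  # 0.0013
#' @export
bonferroniThreshold <- function(alpha, m) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (m < 1) stop("m must be >= 1")
  list(exact = alpha / m, rounded = round(alpha / m, 4))
}
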