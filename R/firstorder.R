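# First-order (intensity histogram) features. Entropy and Uniformity are
# computed on the discretized histogram; everything else on raw intensities.
# Conventions: population variance; uncorrected (Pearson) kurtosis, so a
# normal sample gives ~3; skewness/kurtosis of a constant patch are 0; the
# energy shift constant is 0; log base 2 with 0*log(0) = 0.

#' First-order features of a patch
#'
#' Computes the 18 first-order features: Energy, TotalEnergy, Entropy,
#' Minimum, 10Percentile, 90Percentile, Maximum, Mean, Median,
#' InterquartileRange, Range, MeanAbsoluteDeviation,
#' RobustMeanAbsoluteDeviation, RootMeanSquared, Skewness, Kurtosis,
#' Variance, Uniformity.
#'
#' @param patch Numeric vector/array of voxel intensities (non-empty).
#' @param discretized A \code{discretized_patch} of the same voxels (for
#'   Entropy and Uniformity); computed with default settings if omitted.
#' @param voxel_volume Physical volume of one voxel in mm^3 (for TotalEnergy).
#' @return Named numeric vector of length 18 (names without family prefix).
#' @export
first_order_features <- function(patch, discretized = NULL, voxel_volume = 1) {
  x <- as.vector(patch)
  n <- length(x)
  if (n == 0L) stop("empty patch")
  if (is.null(discretized)) discretized <- discretize(patch)

  p <- tabulate(discretized$levels, nbins = discretized$max_level) / n
  p <- p[p > 0]
  q <- stats::quantile(x, c(0.10, 0.25, 0.50, 0.75, 0.90), names = FALSE,
                       type = 7)
  mu <- mean(x)
  v <- mean((x - mu)^2)                      # population variance
  sk <- if (v > 0) mean((x - mu)^3) / v^1.5 else 0
  ku <- if (v > 0) mean((x - mu)^4) / v^2 else 0
  xr <- x[x >= q[1] & x <= q[5]]             # 10th..90th percentile band
  rmad <- if (length(xr) > 0) mean(abs(xr - mean(xr))) else 0

  c(
    Energy = sum(x^2),
    TotalEnergy = voxel_volume * sum(x^2),
    Entropy = -sum(p * log2(p)),
    Minimum = min(x),
    `10Percentile` = q[1],
    `90Percentile` = q[5],
    Maximum = max(x),
    Mean = mu,
    Median = q[3],
    InterquartileRange = q[4] - q[2],
    Range = max(x) - min(x),
    MeanAbsoluteDeviation = mean(abs(x - mu)),
    RobustMeanAbsoluteDeviation = rmad,
    RootMeanSquared = sqrt(mean(x^2)),
    Skewness = sk,
    Kurtosis = ku,
    Variance = v,
    Uniformity = sum(p^2)
  )
}
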