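#' First-order intensity features
#'
#' The 18 standard first-order features. Entropy and Uniformity are computed
#' on the discretized gray levels; all other features use the raw in-ROI
#' intensities. Percentiles use linear interpolation of order statistics;
#' Variance, Skewness and Kurtosis are population moments (Kurtosis is not
#' excess-corrected); TotalEnergy scales Energy by the voxel volume.
#'
#' @param disc A `fet_disc` from [discretize_roi()].
#' @return Named numeric vector of 18 features (`firstorder_*`).
#' @export
first_order_features <- function(disc) {
  stopifnot(inherits(disc, "fet_disc"))
  x <- disc$values
  n <- length(x)
  vv <- disc$spacing^3
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  p10 <- quantile(x, 0.10, names = FALSE, type = 7)
  p90 <- quantile(x, 0.90, names = FALSE, type = 7)
  robust <- x[x >= p10 & x <= p90]
  p <- tabulate(disc$levels[!is.na(disc$levels)], disc$n_levels) / n
  pp <- p[p > 0]
  skew <- if (m2 > 0) mean((x - mu)^3) / m2^1.5 else 0
  kurt <- if (m2 > 0) mean((x - mu)^4) / m2^2 else 0
  c(
    firstorder_Energy = sum(x^2),
    firstorder_TotalEnergy = vv * sum(x^2),
    firstorder_Entropy = -sum(pp * log2(pp)),
    firstorder_Minimum = min(x),
    firstorder_10Percentile = p10,
    firstorder_90Percentile = p90,
    firstorder_Maximum = max(x),
    firstorder_Mean = mu,
    firstorder_Median = quantile(x, 0.5, names = FALSE, type = 7),
    firstorder_InterquartileRange =
      diff(quantile(x, c(0.25, 0.75), names = FALSE, type = 7)),
    firstorder_Range = max(x) - min(x),
    firstorder_MeanAbsoluteDeviation = mean(abs(x - mu)),
    firstorder_RobustMeanAbsoluteDeviation =
      mean(abs(robust - mean(robust))),
    firstorder_RootMeanSquared = sqrt(mean(x^2)),
    firstorder_Skewness = skew,
    firstorder_Kurtosis = kurt,
    firstorder_Variance = m2,
    firstorder_Uniformity = sum(p^2)
  )
}
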