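#' First-order intensity statistics of a VOI
#'
#' The 18 standard first-order radiomic features. Entropy and Uniformity are
#' computed on the fixed-bin-width discretized intensities (base-2 log);
#' everything else on the raw in-mask values. Skewness and Kurtosis use the
#' population moment ratios (Kurtosis is not excess-corrected: a Gaussian
#' gives ~3). Variance uses the population (1/n) denominator.
#'
#' @param values numeric vector of in-mask intensities.
#' @param bins integer vector of in-mask bin indices (same length); if `NULL`
#'   the values are discretized on the fly with bin width `w`.
#' @param w bin width used when `bins` is `NULL`.
#' @param voxel_volume physical voxel volume in mm^3 (for TotalEnergy).
#' @param prefix name prefix, default `"firstorder_"`.
#' @return named numeric vector of 18 features.
#' @export
first_order_features <- function(values, bins = NULL, w = 5, voxel_volume = 1,
                                 prefix = "firstorder_") {
  if (length(values) < 1) {
    rlang::abort("empty VOI.", class = "lnrad_empty_mask")
  }
  if (is.null(bins)) {
    bins <- as.integer(floor(values / w) - floor(min(values) / w) + 1)
  }
  n <- length(values)
  mu <- mean(values)
  cen <- values - mu
  m2 <- mean(cen^2)
  p <- tabulate(bins) / n
  p <- p[p > 0]
  q <- stats::quantile(values, c(0.1, 0.25, 0.75, 0.9), names = FALSE, type = 7)
  robust <- values[values >= q[1] & values <= q[4]]
  out <- c(
    Mean = mu,
    Median = stats::median(values),
    `10Percentile` = q[1],
    `90Percentile` = q[4],
    InterquartileRange = q[3] - q[2],
    Minimum = min(values),
    Maximum = max(values),
    Range = max(values) - min(values),
    Variance = m2,
    Skewness = if (m2 > 0) mean(cen^3) / m2^1.5 else 0,
    Kurtosis = if (m2 > 0) mean(cen^4) / m2^2 else 0,
    Energy = sum(values^2),
    TotalEnergy = voxel_volume * sum(values^2),
    Entropy = -sum(p * log2(p)),
    Uniformity = sum(p^2),
    MeanAbsoluteDeviation = mean(abs(cen)),
    RobustMeanAbsoluteDeviation = mean(abs(robust - mean(robust))),
    RootMeanSquared = sqrt(mean(values^2))
  )
  names(out) <- paste0(prefix, names(out))
  out
}

firstorder_names <- function(prefix = "firstorder_") {
  paste0(prefix, c("Mean", "Median", "10Percentile", "90Percentile",
                   "InterquartileRange", "Minimum", "Maximum", "Range",
                   "Variance", "Skewness", "Kurtosis", "Energy",
                   "TotalEnergy", "Entropy", "Uniformity",
                   "MeanAbsoluteDeviation", "RobustMeanAbsoluteDeviation",
                   "RootMeanSquared"))
}
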