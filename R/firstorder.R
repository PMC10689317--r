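#' First-order intensity statistics
#'
#' Computes the first-order radiomic features of a set of in-ROI
#' intensities. Conventions follow the reference radiomics definitions:
#'
#' * `Variance` is the population variance (divide by N);
#' * `RMAD` (robust mean absolute deviation) is the mean absolute deviation
#'   from the mean of the values lying within the 10th–90th percentile
#'   inclusive;
#' * `Entropy` is Shannon entropy (bits) of the fixed-bin-width histogram
#'   (`bin_width`, origin at the minimum value);
#' * `Energy` is the sum of squared intensities.
#'
#' All outputs are invariant to permutations of the input.
#'
#' @param values numeric vector of in-ROI intensities (>= 1 value).
#' @param bin_width histogram bin width for `Entropy`.
#' @return Named numeric vector of features.
#' @export
first_order_features <- function(values, bin_width = 5) {
  if (!length(values)) abort("no values supplied")
  n <- length(values)
  m <- mean(values)
  pop_var <- mean((values - m)^2)
  q <- quantile(values, c(0.10, 0.25, 0.75, 0.90), type = 7, names = FALSE)
  robust <- values[values >= q[1] & values <= q[4]]
  rmad <- if (length(robust)) mean(abs(robust - mean(robust))) else 0
  lev <- floor((values - min(values)) / bin_width) + 1
  p <- tabulate(lev) / n
  p <- p[p > 0]
  c(
    Mean = m,
    Median = median(values),
    Minimum = min(values),
    Maximum = max(values),
    Range = max(values) - min(values),
    InterquartileRange = q[3] - q[2],
    Variance = pop_var,
    MeanAbsoluteDeviation = mean(abs(values - m)),
    RMAD = rmad,
    RootMeanSquared = sqrt(mean(values^2)),
    Energy = sum(values^2),
    Entropy = -sum(p * log2(p)),
    Skewness = if (pop_var > 0) mean((values - m)^3) / pop_var^1.5 else 0,
    Kurtosis = if (pop_var > 0) mean((values - m)^4) / pop_var^2 else 0
  )
}
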