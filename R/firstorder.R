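# First-order (histogram/intensity distribution) features.

#' First-order intensity features
#'
#' The standard 18-feature first-order set: moments and order statistics of
#' the raw in-mask intensities plus Entropy (\eqn{-\sum_i p(i) \log_2 p(i)})
#' and Uniformity (\eqn{F_u = \sum_i p(i)^2}) of the discretized gray-level
#' histogram. Kurtosis is uncorrected (a Gaussian scores about 3); Skewness
#' and Kurtosis of a constant region are 0. With `include_sd = TRUE` a 19th
#' feature, StandardDeviation, is appended (used by the histology bank).
#'
#' @param d a [discretize()] result.
#' @param include_sd append StandardDeviation as a 19th feature.
#' @return named numeric vector (`firstorder__*`).
#' @export
first_order <- function(d, include_sd = FALSE) {
  x <- d$values
  n <- length(x)
  p <- tabulate(d$levels[d$levels > 0L], nbins = d$ng) / n
  pnz <- p[p > 0]
  mu <- mean(x)
  v <- mean((x - mu)^2)       # population variance, as is standard here
  q <- quantile(x, c(0.10, 0.25, 0.50, 0.75, 0.90), names = FALSE, type = 7)
  rob <- x[x >= q[1] & x <= q[5]]
  voxvol <- prod(d$spacing)
  f <- c(
    Energy = sum(x^2),
    TotalEnergy = voxvol * sum(x^2),
    Entropy = -sum(pnz * log2(pnz)),
    Minimum = min(x),
    TenthPercentile = q[1],
    NinetiethPercentile = q[5],
    Maximum = max(x),
    Mean = mu,
    Median = q[3],
    InterquartileRange = q[4] - q[2],
    Range = max(x) - min(x),
    MeanAbsoluteDeviation = mean(abs(x - mu)),
    RobustMeanAbsoluteDeviation = mean(abs(rob - mean(rob))),
    RootMeanSquared = sqrt(mean(x^2)),
    Skewness = if (v > 0) mean((x - mu)^3) / v^1.5 else 0,
    Kurtosis = if (v > 0) mean((x - mu)^4) / v^2 else 0,
    Variance = v,
    Uniformity = sum(p^2)
  )
  if (include_sd) f <- c(f, StandardDeviation = sqrt(v))
  names(f) <- paste0("firstorder__", c(FIRSTORDER_NAMES, if (include_sd) "StandardDeviation"))
  f
}
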