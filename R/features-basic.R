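# Linear, moment and cardiopulmonary-ratio features.

#' Amplitude coefficient
#'
#' Root-mean-square amplitude relative to the peak-to-peak range:
#' `rms(x) / (max(x) - min(x))`. Scale-invariant; undefined for a constant
#' series.
#'
#' @param x Numeric series.
#' @return Scalar amplitude coefficient.
#' @examples
#' amplitude_coefficient(sin(seq(0, 2 * pi, length.out = 1000))) # ~ 0.354
#' @export
amplitude_coefficient <- function(x) {
  rng <- max(x) - min(x)
  if (rng == 0) abort_undefined("amplitude coefficient of a constant series")
  sqrt(mean(x^2)) / rng
}

#' Mean signal power
#'
#' @param x Numeric series.
#' @return `mean(x^2)`.
#' @export
signal_power <- function(x) {
  if (length(x) == 0) abort("empty series", class = "bcghf_invalid_argument")
  mean(x^2)
}

#' Summary statistics of a per-segment feature series
#'
#' The four volatility statistics used for every windowed feature: mean,
#' sample (n-1) standard deviation, interquartile range (linear-interpolation
#' quantiles) and median.
#'
#' @param values Per-segment feature values (length >= 2 for the sd).
#' @return A named numeric vector `c(mean, sd, iqr, median)`.
#' @export
windowed_stats <- function(values) {
  if (length(values) < 2) {
    abort("need at least two segments", class = "bcghf_invalid_argument")
  }
  q <- quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
  c(mean = mean(values), sd = sd(values), iqr = q[2] - q[1],
    median = median(values))
}

#' Sample skewness and kurtosis
#'
#' Moment-based shape statistics `m3 / m2^(3/2)` and `m4 / m2^2`, with `mk`
#' the k-th sample moment about the mean. Kurtosis is reported raw (a
#' Gaussian scores 3), not as excess kurtosis.
#'
#' @param x Numeric series with positive variance.
#' @return Scalar skewness or kurtosis.
#' @export
skewness <- function(x) {
  m2 <- mean((x - mean(x))^2)
  if (m2 == 0) abort_undefined("skewness of a constant series")
  mean((x - mean(x))^3) / m2^1.5
}

#' @rdname skewness
#' @export
kurtosis <- function(x) {
  m2 <- mean((x - mean(x))^2)
  if (m2 == 0) abort_undefined("kurtosis of a constant series")
  mean((x - mean(x))^4) / m2^2
}

#' Cardiopulmonary amplitude and power ratios
#'
#' `amp_ratio()` is the ratio of the respiratory to the BCG amplitude
#' coefficient; `power_ratio()` is the ratio of mean signal powers, computed
#' on the raw separated signals (not z-scored, so the physiological relative
#' strength is preserved).
#'
#' @param res,bcg Separated respiratory and BCG series.
#' @return Scalar ratio.
#' @export
amp_ratio <- function(res, bcg) {
  amplitude_coefficient(res) / amplitude_coefficient(bcg)
}

#' @rdname amp_ratio
#' @export
power_ratio <- function(res, bcg) {
  pb <- signal_power(bcg)
  if (pb == 0) abort_undefined("power ratio with zero-power BCG")
  signal_power(res) / pb
}

#' Summed cardiorespiratory fuzzy entropy
#'
#' `fuzzy_entropy(res) + fuzzy_entropy(bcg)`: the overall complexity of the
#' two separated channels.
#'
#' @inheritParams amp_ratio
#' @param m Embedding dimension.
#' @param r Similarity tolerance as a fraction of each series' s.d.
#' @return Scalar entropy sum.
#' @export
fe_sum <- function(res, bcg, m = 2, r = 0.15) {
  fuzzy_entropy(res, m, r) + fuzzy_entropy(bcg, m, r)
}
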