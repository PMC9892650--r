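# Non-linear (chaos and information) features.

#' Fuzzy entropy
#'
#' `-ln(C^(m+1)(r) / C^m(r))`: the negative log ratio of mean pairwise fuzzy
#' memberships between delay-embedded templates of dimension `m + 1` and
#' `m`. Templates are baselined by their own mean, similarity is the
#' exponential membership `exp(-(d / r_abs)^2)` of the Chebyshev distance,
#' self-matches are excluded, and `r_abs = r * sd(x)` so the measure is
#' amplitude-invariant. A constant series has entropy 0; if no
#' `(m+1)`-dimensional matches survive, the value is capped at the log of
#' the number of template pairs (with a warning).
#'
#' @param x Numeric series (length >= m + 2).
#' @param m Embedding dimension (default 2).
#' @param r Similarity tolerance as a fraction of `sd(x)` (default 0.15).
#' @return Scalar fuzzy entropy (>= 0).
#' @examples
#' fuzzy_entropy(rnorm(500)) > fuzzy_entropy(sin(1:500 / 5))
#' @export
fuzzy_entropy <- function(x, m = 2, r = 0.15) {
  if (length(x) < m + 2) {
    abort("series too short for fuzzy entropy", class = "bcghf_invalid_argument")
  }
  s <- sd(x)
  if (s == 0) return(0)
  phi <- cpp_fuzzy_phi(as.numeric(x), as.integer(m), r * s)
  if (phi[2] <= 0 || phi[1] <= 0) {
    nt <- length(x) - m
    cap <- log(nt * (nt - 1) / 2)
    warn("no template matches at dimension m + 1; fuzzy entropy capped")
    return(cap)
  }
  max(-log(phi[2] / phi[1]), 0)
}

#' Per-segment fuzzy entropy series
#'
#' Applies [fuzzy_entropy()] to every sliding-window segment; the tolerance
#' scales with each segment's own standard deviation.
#'
#' @param x Numeric series.
#' @param spec A [window_spec()] for `length(x)`.
#' @inheritParams fuzzy_entropy
#' @return Numeric vector of length `spec$L`.
#' @export
fe_series <- function(x, spec, m = 2, r = 0.15) {
  segs <- segment_signal(x, spec)
  apply(segs, 2, fuzzy_entropy, m = m, r = r)
}

#' Largest Lyapunov exponent
#'
#' Rosenstein-style estimate: the series is delay-embedded, each point is
#' paired with its nearest neighbour outside a Theiler exclusion window, and
#' the mean log distance between paired trajectories is tracked over `i`
#' discrete steps. The exponent is the slope of the initial linear region of
#' that divergence curve, divided by the sampling interval, so the result is
#' a rate per second (per step when `fs = 1`).
#'
#' @param x Numeric series.
#' @param fs Sampling rate (Hz); 1 treats the series as a map.
#' @param emb_dim Embedding dimension (default 12).
#' @param tau Embedding delay in samples; default `round(0.04 * fs)` (40 ms),
#'   floored at 1.
#' @param theiler Theiler exclusion window in samples; default one dominant
#'   period of the series.
#' @param max_steps Length of the tracked divergence curve; default twice
#'   the dominant period (at least 20 steps).
#' @param fit_steps Integer range of steps for the linear fit, or `NULL` to
#'   select the initial region adaptively (up to where the curve has climbed
#'   75% of its total rise).
#' @return Scalar exponent (per second).
#' @examples
#' x <- numeric(1000); x[1] <- 0.4
#' for (i in 2:1000) x[i] <- 4 * x[i - 1] * (1 - x[i - 1])
#' largest_lyapunov(x, fs = 1, emb_dim = 2, tau = 1, theiler = 10) # ~ log(2)
#' @export
largest_lyapunov <- function(x, fs = 1, emb_dim = 12, tau = NULL,
                             theiler = NULL, max_steps = NULL,
                             fit_steps = NULL) {
  x <- as.numeric(x)
  tau <- tau %||% max(1L, as.integer(round(0.04 * fs)))
  period <- dominant_period(x)
  theiler <- theiler %||% period
  max_steps <- max_steps %||% max(20L, 2L * period)
  M <- length(x) - (emb_dim - 1L) * tau
  if (M < theiler + 10L) {
    abort_undefined("series too short for the requested embedding")
  }
  max_steps <- min(max_steps, M - 2L)
  g <- cpp_lle_divergence(x, as.integer(emb_dim), as.integer(tau),
                          as.integer(theiler), as.integer(max_steps))
  if (all(is.na(g))) abort_undefined("no valid neighbour pairs")
  if (is.null(fit_steps)) {
    rise <- max(g, na.rm = TRUE) - g[2]
    k <- which(g - g[2] >= 0.75 * rise)[1]
    fit_steps <- seq(1L, max(4L, min(k, max_steps)))
  }
  fit_steps <- fit_steps[fit_steps + 1L <= length(g)]
  gv <- g[fit_steps + 1L]
  ok <- is.finite(gv)
  if (sum(ok) < 2) abort_undefined("divergence curve too short to fit")
  slope <- unname(coef(lm(gv[ok] ~ fit_steps[ok]))[2])
  slope * fs
}

#' Correlation dimension
#'
#' Grassberger-Procaccia estimate: the correlation sum `C(r)` (fraction of
#' embedded point pairs within Chebyshev distance `r`, outside a Theiler
#' window) is evaluated on a log-spaced radius grid, and the dimension is
#' the slope of `ln C(r)` versus `ln r` in the scaling region
#' (`C` between `c_bounds`, which excludes both the near-recurrence floor
#' and the large-radius saturation). The slope is computed for every
#' embedding dimension in `emb_dims`; the reported estimate is the slope at
#' the first dimension where it has saturated (next increment below 5%),
#' falling back to the largest dimension for non-saturating (noise-like)
#' series.
#'
#' @inheritParams largest_lyapunov
#' @param emb_dims Embedding dimensions scanned (default 2:12).
#' @param n_radii Size of the log-spaced radius grid.
#' @param c_bounds Correlation-sum bounds of the scaling region.
#' @param n_ref Number of reference points (subsampled for speed).
#' @param profile If `TRUE`, return a tibble of per-dimension slopes
#'   instead of the scalar estimate.
#' @return Scalar dimension estimate, or a tibble when `profile = TRUE`.
#' @examples
#' correlation_dimension(sin(2 * pi * (1:2000) / 20.7), tau = 5) # ~ 1
#' @export
correlation_dimension <- function(x, emb_dims = 2:12, fs = 1, tau = NULL,
                                  theiler = NULL, n_radii = 32,
                                  c_bounds = c(0.01, 0.3), n_ref = 500,
                                  profile = FALSE) {
  x <- as.numeric(x)
  tau <- tau %||% max(1L, as.integer(round(0.04 * fs)))
  theiler <- theiler %||% dominant_period(x)
  mmax <- max(emb_dims)
  if (length(x) - (mmax - 1L) * tau < theiler + 10L) {
    abort_undefined("series too short for the requested embedding")
  }
  rng <- max(x) - min(x)
  if (rng == 0) abort_undefined("correlation dimension of a constant series")
  radii <- exp(seq(log(rng / 1000), log(rng), length.out = n_radii))
  C <- cpp_corr_sums(x, as.integer(mmax), as.integer(tau),
                     as.integer(theiler), radii, as.integer(n_ref))
  slopes <- vapply(emb_dims, function(m) {
    cv <- C[m, ]
    keep <- cv >= c_bounds[1] & cv <= c_bounds[2]
    if (sum(keep) < 3) return(NA_real_)
    unname(coef(lm(log(cv[keep]) ~ log(radii[keep])))[2])
  }, numeric(1))
  if (profile) {
    return(tibble(emb_dim = emb_dims, slope = slopes))
  }
  ok <- which(is.finite(slopes))
  if (length(ok) == 0) {
    abort_undefined("fewer than 3 radii in the scaling region")
  }
  for (i in seq_len(length(emb_dims) - 1L)) {
    if (is.finite(slopes[i]) && is.finite(slopes[i + 1L]) &&
        abs(slopes[i + 1L] - slopes[i]) < 0.05 * abs(slopes[i])) {
      return(slopes[i])
    }
  }
  slopes[ok[length(ok)]]
}

#' Maximal information coefficient
#'
#' The MINE-family statistic: the maximum, over axis-aligned grids with
#' `p * q <= length(x)^alpha` bins, of the grid mutual information
#' normalized by `log(min(p, q))`. The x-axis partition for each y-axis
#' equipartition is optimised by dynamic programming over clumps, both axis
#' orientations are searched, and the result lies in `[0, 1]` (0: no
#' association, 1: a noiseless functional relationship).
#'
#' @param x,y Numeric series of equal length (>= 20).
#' @param alpha Grid-budget exponent, `B = n^alpha` (default 0.6).
#' @param clump_factor Superclump budget per column for the dynamic
#'   programme (default 5).
#' @return Scalar MIC in `[0, 1]`.
#' @examples
#' x <- rnorm(200); mic(x, 2 * x + 3) # 1
#' @export
mic <- function(x, y, alpha = 0.6, clump_factor = 5) {
  if (length(x) != length(y)) {
    abort("series must have equal length", class = "bcghf_invalid_argument")
  }
  if (length(x) < 20) {
    abort("MIC requires at least 20 samples", class = "bcghf_invalid_argument")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    warn("constant input series; MIC set to 0")
    return(0)
  }
  cpp_mic(as.numeric(x), as.numeric(y), alpha, clump_factor)
}

#' MIC volatility series over adjacent segments
#'
#' Value `k` is the MIC between sliding-window segments `k` and `k + 1`,
#' giving `L - 1` values that track how quickly the signal's short-range
#' structure decorrelates.
#'
#' @inheritParams fe_series
#' @inheritParams mic
#' @return Numeric vector of length `spec$L - 1`.
#' @export
mic_series <- function(x, spec, alpha = 0.6, clump_factor = 5) {
  if (spec$L < 2) {
    abort("need at least two segments for a MIC series",
          class = "bcghf_invalid_argument")
  }
  segs <- segment_signal(x, spec)
  vapply(seq_len(spec$L - 1L), function(k) {
    mic(segs[, k], segs[, k + 1L], alpha, clump_factor)
  }, numeric(1))
}
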