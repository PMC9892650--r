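# Sliding-window segmentation shared by all volatility features.

#' Sliding-window specification
#'
#' Describes how a length-`n` series is cut into `L` segments of `w` seconds
#' advanced by `t` seconds: `L = fix((n - w*fs + t*fs) / (t*fs))`, with
#' `fix` the truncation toward zero. Segments overlap when `t < w`.
#'
#' @param w Window length (s).
#' @param t Time moving factor (s).
#' @param fs Sampling rate (Hz).
#' @param n Series length (samples).
#' @return A list of class `bcg_window_spec` with fields `w`, `t`, `fs`,
#'   `n`, and the derived segment count `L`.
#' @examples
#' window_spec(4, 3, 1000, 30000)$L # 9
#' @export
window_spec <- function(w, t, fs, n) {
  stopifnot_positive(w, "w")
  stopifnot_positive(t, "t")
  stopifnot_positive(fs, "fs")
  wn <- w * fs
  tn <- t * fs
  if (abs(wn - round(wn)) > 1e-8 || abs(tn - round(tn)) > 1e-8) {
    abort("w*fs and t*fs must be whole numbers of samples",
          class = "bcghf_invalid_argument")
  }
  wn <- as.integer(round(wn))
  tn <- as.integer(round(tn))
  if (wn > n) {
    abort("window longer than series", class = "bcghf_invalid_argument")
  }
  L <- trunc((n - wn + tn) / tn)
  if (L < 1) {
    abort("window specification yields no segments",
          class = "bcghf_invalid_argument")
  }
  structure(list(w = w, t = t, fs = fs, n = n, wn = wn, tn = tn, L = L),
            class = "bcg_window_spec")
}

#' Cut a series into sliding-window segments
#'
#' Segment `i` (1-based) starts at sample `(i - 1) * t * fs + 1` and spans
#' `w * fs` samples.
#'
#' @param x Numeric series of the length declared in `spec`.
#' @param spec A [window_spec()].
#' @return A `w*fs` x `L` matrix, one segment per column.
#' @export
segment_signal <- function(x, spec) {
  if (length(x) != spec$n) {
    abort("series length does not match the window specification",
          class = "bcghf_invalid_argument")
  }
  starts <- (seq_len(spec$L) - 1L) * spec$tn + 1L
  vapply(starts, function(s) x[s:(s + spec$wn - 1L)], numeric(spec$wn))
}
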