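# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    abort("`seed` must be a single integer", class = "bcghf_invalid_argument")
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# n reproducible child seeds (< 2^31) derived from one master seed
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

stopifnot_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x <= 0) {
    abort(sprintf("`%s` must be a single positive number", name),
          class = "bcghf_invalid_argument")
  }
  invisible(x)
}

# Zero-phase filtering with reflection padding to suppress edge transients.
filtfilt_pad <- function(filt, x, pad = NULL) {
  n <- length(x)
  if (is.null(pad)) pad <- min(n - 1L, 5000L)
  if (pad > 0) {
    left <- 2 * x[1] - x[seq(pad + 1L, 2L)]
    right <- 2 * x[n] - x[seq(n - 1L, n - pad)]
    y <- signal::filtfilt(filt, c(left, x, right))
    y[seq(pad + 1L, pad + n)]
  } else {
    signal::filtfilt(filt, x)
  }
}

# Zero-phase anti-aliased decimation to an integer divisor of fs.
decimate_signal <- function(x, fs, fs_out) {
  stopifnot_positive(fs, "fs")
  stopifnot_positive(fs_out, "fs_out")
  q <- fs / fs_out
  if (abs(q - round(q)) > 1e-8) {
    abort("`fs_out` must divide `fs`", class = "bcghf_invalid_argument")
  }
  q <- as.integer(round(q))
  if (q == 1L) return(x)
  lp <- signal::butter(4, 0.8 * (fs_out / 2) / (fs / 2))
  y <- filtfilt_pad(lp, x)
  y[seq(1L, length(y), by = q)]
}

# Dominant period of an oscillatory series, in samples: lag of the first
# autocorrelation maximum after the first zero crossing (fallback: four
# times the first zero crossing, then n/4).
dominant_period <- function(x, max_lag = NULL) {
  n <- length(x)
  if (is.null(max_lag)) max_lag <- min(n - 2L, 5000L)
  a <- acf(x, lag.max = max_lag, plot = FALSE, demean = TRUE)$acf[-1]
  zc <- which(a <= 0)[1]
  if (is.na(zc)) return(max(2L, n %/% 4L))
  if (zc < length(a)) {
    seg <- a[seq(zc, length(a))]
    pk <- which(diff(sign(diff(seg))) < 0) + 1L
    if (length(pk) > 0 && seg[pk[1]] > 0) return(zc + pk[1] - 1L)
  }
  max(2L, min(4L * zc, n %/% 2L))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_undefined <- function(msg) {
  abort(msg, class = "bcghf_undefined_feature")
}
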