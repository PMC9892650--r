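# Signal separation, artifact screening, epoching and quality scoring.

# resolve (samples, fs) from a bcg_recording or a numeric vector + fs
resolve_signal <- function(x, fs = NULL) {
  if (inherits(x, "bcg_recording")) {
    list(x = as.numeric(x$counts), fs = recording_fs(x),
         subject_id = recording_subject(x), label = recording_label(x))
  } else {
    if (is.null(fs)) {
      abort("`fs` must be supplied when `x` is not a bcg_recording",
            class = "bcghf_invalid_argument")
    }
    list(x = as.numeric(x), fs = fs, subject_id = NA_character_,
         label = NA_integer_)
  }
}

#' Flag movement artifacts by peak-to-mean ratio
#'
#' The raw signal is cut into non-overlapping 1-s windows; each window is
#' centred on its own mean and scored by the peak-to-mean ratio
#' `pmr = max(|x - mean|) / mean(|x - mean|)`. Windows whose pmr exceeds the
#' threshold are flagged and later excluded from epoching. A clean
#' oscillatory window scores close to the sinusoidal value pi/2 ~ 1.57; a
#' short high-amplitude spike drives the ratio far above any clean window.
#' An all-constant window is defined to score 1 and is never flagged.
#'
#' @param x A `bcg_recording` or numeric signal.
#' @param pmr_threshold Flagging threshold (dimensionless, default 6).
#' @param fs Sampling rate (Hz); taken from the recording when omitted.
#' @return A tibble of class `bcg_artifact_mask` with one row per whole 1-s
#'   window: `window`, `t_start`, `pmr`, `flagged`. A trailing remainder
#'   shorter than 1 s is not scored.
#' @examples
#' detect_artifacts(sin(2 * pi * 2 * seq(0, 3, by = 0.01)), fs = 100)
#' @export
detect_artifacts <- function(x, pmr_threshold = 6, fs = NULL) {
  sig <- resolve_signal(x, fs)
  n <- length(sig$x)
  w <- as.integer(round(sig$fs))
  if (n < w) {
    abort("signal must be at least 1 s long", class = "bcghf_invalid_argument")
  }
  nwin <- n %/% w
  pmr <- vapply(seq_len(nwin), function(i) {
    xi <- sig$x[((i - 1L) * w + 1L):(i * w)]
    xc <- abs(xi - mean(xi))
    m <- mean(xc)
    if (m == 0) 1 else max(xc) / m
  }, numeric(1))
  out <- tibble(window = seq_len(nwin), t_start = (seq_len(nwin) - 1),
                pmr = pmr, flagged = pmr > pmr_threshold)
  attr(out, "pmr_threshold") <- pmr_threshold
  attr(out, "fs") <- sig$fs
  class(out) <- c("bcg_artifact_mask", class(out))
  out
}

#' Separate the respiratory effort component
#'
#' Grayscale morphological smoothing - the average of an opening and a
#' closing with a flat structuring element of `se_seconds` (longer than any
#' beat complex, much shorter than a breath) - strips the oscillatory BCG
#' content, and a zero-phase low-pass Butterworth filter removes what
#' remains above the respiration band.
#'
#' @inheritParams detect_artifacts
#' @param se_seconds Flat structuring-element length (s).
#' @param cutoff_hz Low-pass cut-off (Hz).
#' @param order Butterworth order (applied forward-backward, so the
#'   effective magnitude response is of twice this order).
#' @return Numeric respiratory effort series, same length as the input.
#' @export
extract_respiration <- function(x, se_seconds = 1, cutoff_hz = 1, order = 4,
                                fs = NULL) {
  sig <- resolve_signal(x, fs)
  k <- as.integer(round(se_seconds * sig$fs))
  if (k %% 2L == 0L) k <- k + 1L
  if (k > length(sig$x)) {
    abort("structuring element longer than signal",
          class = "bcghf_invalid_argument")
  }
  opening <- cpp_running_max(cpp_running_min(sig$x, k), k)
  closing <- cpp_running_min(cpp_running_max(sig$x, k), k)
  morph <- (opening + closing) / 2
  lp <- signal::butter(order, cutoff_hz / (sig$fs / 2))
  filtfilt_pad(lp, morph)
}

#' Recover the BCG component
#'
#' Subtracts the separated respiratory effort from the raw signal and
#' applies a 4th-order Butterworth band-pass (2-8.5 Hz), forward-backward
#' for zero phase. The output is zero-mean.
#'
#' @inheritParams detect_artifacts
#' @param res Respiratory effort series (same length as the raw signal).
#' @param band Pass band (Hz).
#' @param order Butterworth order (single pass).
#' @return Numeric BCG series, same length as the input.
#' @export
extract_bcg <- function(x, res, band = c(2, 8.5), order = 4, fs = NULL) {
  sig <- resolve_signal(x, fs)
  if (length(res) != length(sig$x)) {
    abort("`res` must have the same length as the raw signal",
          class = "bcghf_invalid_argument")
  }
  if (sig$fs < 2 * band[2]) {
    abort("sampling rate below twice the upper band edge",
          class = "bcghf_invalid_argument")
  }
  bp <- signal::butter(order, band / (sig$fs / 2), type = "pass")
  y <- filtfilt_pad(bp, sig$x - res)
  y - mean(y)
}

#' Cut aligned 30-s epoch pairs
#'
#' Consecutive, non-overlapping `epoch_seconds` windows are taken on a fixed
#' grid from the start of the recording. An epoch that contains any flagged
#' 1-s artifact window is dropped (features assume stationarity over the
#' epoch); a trailing remainder shorter than one epoch is discarded.
#' Retained epochs keep their grid position as `epoch_index`.
#'
#' @param bcg,res Aligned separated signals.
#' @param mask A `bcg_artifact_mask` from [detect_artifacts()], or `NULL` to
#'   keep all epochs.
#' @param fs Sampling rate (Hz).
#' @param subject_id,label Provenance carried into the result.
#' @param epoch_seconds Epoch length (s, default 30).
#' @return A tibble with one row per retained epoch: `subject_id`, `label`,
#'   `epoch_index`, `fs`, and list-columns `bcg`, `res`.
#' @export
epoch_signals <- function(bcg, res, mask = NULL, fs, subject_id = NA_character_,
                          label = NA_integer_, epoch_seconds = 30) {
  if (length(bcg) != length(res)) {
    abort("`bcg` and `res` must be aligned", class = "bcghf_invalid_argument")
  }
  ns <- as.integer(round(epoch_seconds * fs))
  n_epochs <- length(bcg) %/% ns
  if (n_epochs == 0) {
    return(tibble(subject_id = character(), label = integer(),
                  epoch_index = integer(), fs = numeric(),
                  bcg = list(), res = list()))
  }
  flagged_sec <- if (is.null(mask)) integer(0) else mask$window[mask$flagged]
  keep <- vapply(seq_len(n_epochs), function(i) {
    secs <- ((i - 1L) * epoch_seconds + 1L):(i * epoch_seconds)
    !any(secs %in% flagged_sec)
  }, logical(1))
  rows <- purrr::map(which(keep), function(i) {
    idx <- ((i - 1L) * ns + 1L):(i * ns)
    tibble(subject_id = subject_id, label = label, epoch_index = i, fs = fs,
           bcg = list(bcg[idx]), res = list(res[idx]))
  })
  dplyr::bind_rows(rows)
}

#' Score BCG epoch quality as a periodicity SNR
#'
#' Measures whether the epoch contains a recognizable beat sequence without
#' locating any heartbeat. The smoothed amplitude envelope of the BCG
#' (rectified signal, low-passed at 2 Hz) is autocorrelated inside short
#' overlapping local windows; within each window the maximum normalized
#' autocorrelation over lags 0.3-2.0 s (the physiological beat-period
#' range) scores the local beat periodicity, and rho is the median over
#' windows. Windowing makes the score tolerant of the slow heart-rate
#' modulation seen in real rhythms - the beat lag only has to be locally
#' consistent - while an envelope without beat structure (noise, disordered
#' cardiac motion) scores low everywhere. rho is mapped to decibels as
#' `10 log10(rho / (1 - rho))`, clipped to `[-20, 40]`; a zero-variance
#' epoch scores -20 dB.
#'
#' @param x BCG epoch (numeric).
#' @param fs Sampling rate (Hz).
#' @param lag_range Beat-period search range (s).
#' @param window_seconds Local analysis window (s); windows overlap by half.
#' @return SNR in dB.
#' @examples
#' estimate_snr(rnorm(3000), fs = 100) # noise scores < 0 dB
#' @export
estimate_snr <- function(x, fs, lag_range = c(0.3, 2), window_seconds = 6) {
  if (sd(x) == 0) return(-20)
  lp <- signal::butter(2, min(2 / (fs / 2), 0.99))
  env <- filtfilt_pad(lp, abs(x))
  e <- env - mean(env)
  if (sd(e) == 0) return(-20)
  n <- length(e)
  wn <- min(n, as.integer(round(window_seconds * fs)))
  hop <- max(1L, wn %/% 2L)
  starts <- seq(1L, max(1L, n - wn + 1L), by = hop)
  rho_local <- vapply(starts, function(s0) {
    w <- e[s0:(s0 + wn - 1L)]
    w <- w - mean(w)
    if (sd(w) == 0) return(0)
    lags <- max(1L, floor(lag_range[1] * fs)):
      min(wn - 2L, ceiling(lag_range[2] * fs))
    m <- nextn(2L * wn, 2)
    f <- fft(c(w, rep(0, m - wn)))
    ac <- Re(fft(f * Conj(f), inverse = TRUE))[seq_len(max(lags) + 1L)]
    ac <- ac / (wn - 0:max(lags)) # lag-unbiased normalization
    max(ac[lags + 1L] / ac[1L])
  }, numeric(1))
  snr_from_rho(median(rho_local))
}

#' @rdname estimate_snr
#' @param rho A periodicity score in `[0, 1]`.
#' @return `snr_from_rho()`: `10 log10(rho / (1 - rho))` clipped to
#'   `[-20, 40]` dB.
#' @examples
#' snr_from_rho(0.715) # 4.0 dB
#' @export
snr_from_rho <- function(rho) {
  if (rho <= 0) return(-20)
  if (rho >= 1) return(40)
  min(max(10 * log10(rho / (1 - rho)), -20), 40)
}

#' Stratify epochs into quality-based dataset groups
#'
#' HF epochs with `snr_db >=` the threshold (recognizable heartbeat) form
#' dataset 1; HF epochs below it (unrecognizable heartbeat) form dataset 2;
#' every non-HF epoch is a control in both groups.
#'
#' @param epochs An epoch tibble with `label` and `snr_db` columns.
#' @param snr_threshold_db Quality gate in dB (default 4).
#' @return A list with tibbles `dataset1` and `dataset2`.
#' @export
split_datasets <- function(epochs, snr_threshold_db = 4) {
  if (!all(c("label", "snr_db") %in% names(epochs))) {
    abort("`epochs` must carry `label` and `snr_db` columns",
          class = "bcghf_invalid_argument")
  }
  hf <- epochs[epochs$label == 1L, , drop = FALSE]
  ctrl <- epochs[epochs$label == 0L, , drop = FALSE]
  list(dataset1 = dplyr::bind_rows(hf[hf$snr_db >= snr_threshold_db, ], ctrl),
       dataset2 = dplyr::bind_rows(hf[hf$snr_db < snr_threshold_db, ], ctrl))
}

#' Preprocess one recording into scored epoch pairs
#'
#' Runs artifact detection, respiration separation, BCG recovery, epoching
#' and SNR scoring in sequence.
#'
#' @param rec A `bcg_recording`.
#' @param pmr_threshold Artifact peak-to-mean-ratio threshold.
#' @param se_seconds,resp_cutoff_hz,filter_order Respiration separation
#'   settings (see [extract_respiration()]).
#' @param band BCG band-pass edges (Hz).
#' @param epoch_seconds Epoch length (s).
#' @return An epoch tibble (see [epoch_signals()]) with an `snr_db` column.
#' @export
preprocess_recording <- function(rec, pmr_threshold = 6, se_seconds = 1,
                                 resp_cutoff_hz = 1, filter_order = 4,
                                 band = c(2, 8.5), epoch_seconds = 30) {
  mask <- detect_artifacts(rec, pmr_threshold)
  res <- extract_respiration(rec, se_seconds, resp_cutoff_hz, filter_order)
  bcg <- extract_bcg(rec, res, band, filter_order)
  ep <- epoch_signals(bcg, res, mask, fs = recording_fs(rec),
                      subject_id = recording_subject(rec),
                      label = recording_label(rec),
                      epoch_seconds = epoch_seconds)
  if (nrow(ep) == 0) return(dplyr::mutate(ep, snr_db = numeric(0)))
  ep$snr_db <- vapply(ep$bcg, estimate_snr, numeric(1), fs = recording_fs(rec))
  ep
}

#' Preprocess a whole cohort
#'
#' @param cohort A cohort tibble from [make_cohort()] (or any tibble with a
#'   `recording` list-column of `bcg_recording`s).
#' @param ... Passed to [preprocess_recording()].
#' @return A combined epoch tibble over all subjects.
#' @export
preprocess_cohort <- function(cohort, ...) {
  dplyr::bind_rows(purrr::map(cohort$recording, preprocess_recording, ...))
}
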