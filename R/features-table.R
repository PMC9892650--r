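# Assembly of the 33-feature vector per epoch.

#' Feature extraction configuration
#'
#' Window pairings, decimation rates and estimator parameters for the
#' 33-feature set. Windowed BCG features share a 4-s window with moving
#' factors of 3 s (power), 2 s (fuzzy entropy) and 1 s (MIC); respiratory
#' fuzzy entropy uses a 6-s window moved by 1 s; the windowed
#' respiration-to-BCG power ratio uses 2-s windows moved by 2 s. The BCG is
#' decimated to 125 Hz and the respiration to 10 Hz before the non-linear
#' features, whose cost grows quadratically with length; the 40-ms embedding
#' delay is then an integer 5 samples for the BCG.
#'
#' @param fs Epoch sampling rate (Hz).
#' @param epoch_seconds Epoch length (s).
#' @param bcg_decim_fs,res_decim_fs Decimation targets for the non-linear
#'   features (Hz).
#' @param power_window,fe_bcg_window,mic_window,fe_res_window,ratio_window
#'   `c(w, t)` window/moving-factor pairs in seconds.
#' @param fe_m,fe_r Fuzzy-entropy embedding dimension and tolerance.
#' @param chaos_emb_dims Embedding dimensions scanned for the correlation
#'   dimension; the largest is also the Lyapunov embedding dimension.
#' @param chaos_tau_s Embedding delay (s).
#' @param mic_alpha,mic_clump_factor MIC grid-budget exponent and clump
#'   budget.
#' @return A list of class `bcg_feature_config`.
#' @export
feature_config <- function(fs = 1000, epoch_seconds = 30,
                           bcg_decim_fs = 125, res_decim_fs = 10,
                           power_window = c(4, 3), fe_bcg_window = c(4, 2),
                           mic_window = c(4, 1), fe_res_window = c(6, 1),
                           ratio_window = c(2, 2),
                           fe_m = 2, fe_r = 0.15,
                           chaos_emb_dims = 2:12, chaos_tau_s = 0.04,
                           mic_alpha = 0.6, mic_clump_factor = 5) {
  structure(
    list(fs = fs, epoch_seconds = epoch_seconds,
         bcg_decim_fs = bcg_decim_fs, res_decim_fs = res_decim_fs,
         power_window = power_window, fe_bcg_window = fe_bcg_window,
         mic_window = mic_window, fe_res_window = fe_res_window,
         ratio_window = ratio_window, fe_m = fe_m, fe_r = fe_r,
         chaos_emb_dims = chaos_emb_dims, chaos_tau_s = chaos_tau_s,
         mic_alpha = mic_alpha, mic_clump_factor = mic_clump_factor),
    class = "bcg_feature_config"
  )
}

#' Names and descriptions of the 33 features
#'
#' @return A tibble with `feature` (t01-t33), `channel`, and `description`.
#' @export
feature_names <- function() {
  tibble(
    feature = sprintf("t%02d", 1:33),
    channel = c(rep("bcg", 18), rep("res", 8), rep("cardiopulmonary", 7)),
    description = c(
      "BCG amplitude coefficient",
      paste("BCG windowed-power", c("mean", "sd", "IQR", "median")),
      "BCG fuzzy entropy",
      paste("BCG windowed fuzzy-entropy", c("mean", "sd", "IQR", "median")),
      "BCG largest Lyapunov exponent",
      "BCG correlation dimension",
      paste("BCG adjacent-segment MIC", c("mean", "sd", "IQR", "median")),
      "BCG skewness", "BCG kurtosis",
      "Respiratory amplitude coefficient",
      "Respiratory fuzzy entropy",
      paste("Respiratory windowed fuzzy-entropy",
            c("mean", "sd", "IQR", "median")),
      "Respiratory skewness", "Respiratory kurtosis",
      "Respiratory-to-BCG amplitude-coefficient ratio",
      "Respiratory-to-BCG power ratio",
      paste("Windowed respiratory-to-BCG power-ratio",
            c("mean", "sd", "IQR", "median")),
      "Summed respiratory + BCG fuzzy entropy"
    )
  )
}

#' Extract the 33-feature vector from one epoch pair
#'
#' Computes the full feature set from an aligned 30-s BCG/respiration pair:
#' the amplitude coefficient and windowed-power statistics (the epoch is
#' z-scored before the power calculation), fuzzy entropy and its windowed
#' statistics, the largest Lyapunov exponent and correlation dimension,
#' adjacent-segment MIC statistics, skewness/kurtosis, the respiratory
#' counterparts, and the cardiopulmonary amplitude/power ratios (computed on
#' the raw separated signals) plus the summed fuzzy entropy. If any feature
#' is undefined (e.g. a constant channel), the returned row is flagged
#' `complete = FALSE`.
#'
#' @param bcg,res Aligned separated epoch signals.
#' @param config A [feature_config()]; its `fs` must match the epoch.
#' @return A one-row tibble with columns `t01`-`t33` and `complete`.
#' @export
extract_features <- function(bcg, res, config = feature_config()) {
  fs <- config$fs
  n <- length(bcg)
  if (length(res) != n) {
    abort("`bcg` and `res` must be aligned", class = "bcghf_invalid_argument")
  }
  v <- stats::setNames(rep(NA_real_, 33), sprintf("t%02d", 1:33))
  complete <- TRUE
  set <- function(idx, expr) {
    val <- tryCatch(expr, bcghf_undefined_feature = function(e) {
      warn(sprintf("undefined feature t%02d: %s", idx[1], conditionMessage(e)))
      complete <<- FALSE
      rep(NA_real_, length(idx))
    })
    v[idx] <<- val
  }

  # linear and moment features at the native rate
  set(1, amplitude_coefficient(bcg))
  z <- (bcg - mean(bcg)) / sd(bcg)
  spec_pow <- window_spec(config$power_window[1], config$power_window[2], fs, n)
  set(2:5, windowed_stats(apply(segment_signal(z, spec_pow), 2, signal_power)))
  set(17, skewness(bcg))
  set(18, kurtosis(bcg))
  set(19, amplitude_coefficient(res))
  set(25, skewness(res))
  set(26, kurtosis(res))
  set(27, amp_ratio(res, bcg))
  set(28, power_ratio(res, bcg))
  spec_ratio <- window_spec(config$ratio_window[1], config$ratio_window[2], fs, n)
  set(29:32, {
    sb <- segment_signal(bcg, spec_ratio)
    sr <- segment_signal(res, spec_ratio)
    ratios <- vapply(seq_len(spec_ratio$L), function(i) {
      power_ratio(sr[, i], sb[, i])
    }, numeric(1))
    windowed_stats(ratios)
  })

  # non-linear features on decimated channels
  bcg_d <- decimate_signal(bcg, fs, config$bcg_decim_fs)
  res_d <- decimate_signal(res, fs, config$res_decim_fs)
  tau_b <- max(1L, as.integer(round(config$chaos_tau_s * config$bcg_decim_fs)))
  set(6, fuzzy_entropy(bcg_d, config$fe_m, config$fe_r))
  spec_feb <- window_spec(config$fe_bcg_window[1], config$fe_bcg_window[2],
                          config$bcg_decim_fs, length(bcg_d))
  set(7:10, windowed_stats(fe_series(bcg_d, spec_feb, config$fe_m, config$fe_r)))
  set(11, largest_lyapunov(bcg_d, fs = config$bcg_decim_fs,
                           emb_dim = max(config$chaos_emb_dims), tau = tau_b))
  set(12, correlation_dimension(bcg_d, emb_dims = config$chaos_emb_dims,
                                fs = config$bcg_decim_fs, tau = tau_b))
  spec_mic <- window_spec(config$mic_window[1], config$mic_window[2],
                          config$bcg_decim_fs, length(bcg_d))
  set(13:16, windowed_stats(mic_series(bcg_d, spec_mic, config$mic_alpha,
                                       config$mic_clump_factor)))
  set(20, fuzzy_entropy(res_d, config$fe_m, config$fe_r))
  spec_fer <- window_spec(config$fe_res_window[1], config$fe_res_window[2],
                          config$res_decim_fs, length(res_d))
  set(21:24, windowed_stats(fe_series(res_d, spec_fer, config$fe_m, config$fe_r)))
  set(33, v["t06"] + v["t20"])

  out <- as_tibble(as.list(v))
  out$complete <- complete && all(is.finite(unlist(v)))
  out
}

#' Extract the feature table for a set of epochs
#'
#' Applies [extract_features()] to every row of an epoch tibble and binds
#' the provenance columns. Epochs with any undefined feature are excluded
#' (with a message); the excluded count is attached as an attribute.
#'
#' @param epochs An epoch tibble from [preprocess_recording()] /
#'   [preprocess_cohort()] (columns `bcg`, `res`, `fs`, `subject_id`,
#'   `label`, `epoch_index`, optionally `snr_db`).
#' @param config A [feature_config()].
#' @return A tibble with `subject_id`, `label`, `epoch_index`, `snr_db`
#'   (when present) and `t01`-`t33`.
#' @export
extract_feature_table <- function(epochs, config = feature_config()) {
  if (nrow(epochs) == 0) {
    abort("no epochs to extract features from",
          class = "bcghf_invalid_argument")
  }
  feats <- purrr::map(seq_len(nrow(epochs)), function(i) {
    cfg <- config
    if (!is.null(epochs$fs) && epochs$fs[i] != cfg$fs) cfg$fs <- epochs$fs[i]
    extract_features(epochs$bcg[[i]], epochs$res[[i]], cfg)
  })
  feats <- dplyr::bind_rows(feats)
  meta_cols <- intersect(c("subject_id", "label", "epoch_index", "snr_db"),
                         names(epochs))
  out <- dplyr::bind_cols(epochs[meta_cols], feats)
  bad <- !out$complete
  if (any(bad)) {
    message(sprintf("excluding %d epoch(s) with undefined features", sum(bad)))
    out <- out[!bad, , drop = FALSE]
  }
  out$complete <- NULL
  attr(out, "excluded") <- sum(bad)
  attr(out, "config") <- config
  out
}
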