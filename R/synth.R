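# Synthetic cardiorespiratory signal generator.
#
# Emulates a piezoelectric force sensor under the head/neck: a quasi-periodic
# BCG beat train (J-peak dominant, energy in the 2-8.5 Hz band), a
# low-frequency respiratory effort component (< 1 Hz), slow baseline drift,
# sparse artifact spikes and white sensor noise, digitised to signed ADC
# counts. Ground-truth components are returned alongside every mixture so
# separation and feature code can be validated without clinical recordings.

# counts per model amplitude unit when digitising (12-bit span is +/- 2048)
.ADC_GAIN <- 150

#' Ballistocardiogram beat template
#'
#' A single beat complex modelled as five Gaussian-windowed sinusoid
#' deflections (the classical H, I, J, K, L waves) sharing one carrier
#' frequency. With the default half-carrier-period wave spacing and
#' alternating deflection signs the waves compose coherently into a smooth
#' amplitude envelope riding on the carrier, which keeps the template's
#' energy inside the 2-8.5 Hz BCG band while preserving the J-peak-dominant
#' morphology.
#'
#' @param wave_amplitudes Signed relative amplitudes of the H, I, J, K, L
#'   deflections (dimensionless; J must have the largest magnitude).
#' @param wave_offsets Wave-centre times relative to beat onset (s).
#' @param wave_widths Gaussian envelope widths (s), all positive.
#' @param carrier_freq Oscillation frequency shared by all deflections (Hz);
#'   must lie strictly inside (2, 8.5).
#' @return An object of class `bcg_beat_template`.
#' @examples
#' tpl <- beat_template()
#' beat_duration(tpl)
#' @export
beat_template <- function(wave_amplitudes = c(H = 0.4, I = -0.6, J = 1, K = -0.5, L = 0.35),
                          wave_offsets = c(0.08, 0.18, 0.28, 0.38, 0.48),
                          wave_widths = c(0.05, 0.05, 0.06, 0.05, 0.05),
                          carrier_freq = 5) {
  if (length(wave_amplitudes) != length(wave_offsets) ||
      length(wave_offsets) != length(wave_widths)) {
    abort("wave amplitude/offset/width vectors must have equal length",
          class = "bcghf_invalid_argument")
  }
  if (any(wave_widths <= 0)) {
    abort("all wave widths must be > 0", class = "bcghf_invalid_argument")
  }
  if (carrier_freq <= 2 || carrier_freq >= 8.5) {
    abort("carrier_freq must lie inside (2, 8.5) Hz",
          class = "bcghf_invalid_argument")
  }
  j <- which.max(abs(wave_amplitudes))
  if (names(wave_amplitudes)[j] %||% "" != "" && length(wave_amplitudes) == 5 &&
      j != 3L) {
    warn("J (third) deflection is conventionally the largest")
  }
  structure(
    list(wave_amplitudes = wave_amplitudes, wave_offsets = wave_offsets,
         wave_widths = wave_widths, carrier_freq = carrier_freq),
    class = "bcg_beat_template"
  )
}

#' @rdname beat_template
#' @param template A `bcg_beat_template`.
#' @return `beat_duration()`: the template's support in seconds (offsets plus
#'   four envelope widths).
#' @export
beat_duration <- function(template) {
  max(template$wave_offsets + 4 * template$wave_widths)
}

# evaluate the template on a time grid (s, relative to beat onset)
eval_template <- function(template, t, amp_factors = NULL, width_factor = 1) {
  a <- template$wave_amplitudes
  if (!is.null(amp_factors)) a <- a * amp_factors
  out <- numeric(length(t))
  for (k in seq_along(a)) {
    dt <- t - template$wave_offsets[k]
    w <- template$wave_widths[k] * width_factor
    out <- out + a[k] * exp(-dt^2 / (2 * w^2)) *
      cos(2 * pi * template$carrier_freq * dt)
  }
  out
}

#' Class-conditional generator parameters
#'
#' One bundle of physiological parameters per diagnostic class. The default
#' heart-failure (HF) and non-HF bundles encode the contrasts the detection
#' scheme relies on: HF subjects have a faster, more irregular heart rhythm,
#' weaker and morphologically more variable BCG complexes, faster and
#' stronger respiratory effort, and a 40% chance per 30-s epoch that the
#' heartbeat is rendered unrecognizable (very low BCG signal-to-noise).
#'
#' @param mean_hr Mean heart rate (beats/min).
#' @param hr_jitter_cv Coefficient of variation of the beat-to-beat period.
#' @param bcg_amp_scale BCG amplitude multiplier (model units).
#' @param morph_jitter Per-beat amplitude/width perturbation s.d. (fraction).
#' @param resp_rate Respiratory rate (breaths/min).
#' @param resp_amp_scale Respiratory amplitude multiplier (model units).
#' @param resp_harmonic_frac Fraction of second-harmonic energy in the
#'   respiratory waveform, in `[0, 1]`.
#' @param resp_am_depth Depth of the slow (~0.015 Hz) amplitude modulation
#'   of breathing, in `[0, 1]`.
#' @param resp_noise_frac Fine-scale stochastic respiratory-effort
#'   component (band-limited below 1 Hz) as a fraction of the waveform
#'   s.d., in `[0, 1]`. Healthy breathing is irregular breath to breath;
#'   the dyspneic breathing of HF is deeper and more stereotyped, so the
#'   HF default is much smaller.
#' @param artifact_rate Expected movement-artifact spikes per minute.
#' @param noise_sd White sensor noise s.d., in ADC counts.
#' @param p_unrecognizable Probability that a 30-s epoch is rendered with a
#'   degraded (unrecognizable-heartbeat) BCG component.
#' @return An object of class `bcg_class_params`.
#' @examples
#' hf_class_params()$mean_hr
#' @export
class_params <- function(mean_hr = 65, hr_jitter_cv = 0.04, bcg_amp_scale = 1,
                         morph_jitter = 0.05, resp_rate = 14,
                         resp_amp_scale = 0.8, resp_harmonic_frac = 0.2,
                         resp_am_depth = 0.3, resp_noise_frac = 0.25,
                         artifact_rate = 0.2, noise_sd = 10,
                         p_unrecognizable = 0) {
  for (nm in c("mean_hr", "hr_jitter_cv", "bcg_amp_scale", "resp_rate",
               "resp_amp_scale", "artifact_rate")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || is.na(v) ||
        v < 0 || (v == 0 && nm %in% c("mean_hr", "bcg_amp_scale",
                                      "resp_rate", "resp_amp_scale"))) {
      abort(sprintf("`%s` must be positive", nm),
            class = "bcghf_invalid_argument")
    }
  }
  for (nm in c("resp_harmonic_frac", "resp_am_depth", "resp_noise_frac",
               "p_unrecognizable")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1) {
      abort(sprintf("`%s` must lie in [0, 1]", nm),
            class = "bcghf_invalid_argument")
    }
  }
  if (morph_jitter < 0 || noise_sd < 0) {
    abort("`morph_jitter` and `noise_sd` must be >= 0",
          class = "bcghf_invalid_argument")
  }
  structure(
    list(mean_hr = mean_hr, hr_jitter_cv = hr_jitter_cv,
         bcg_amp_scale = bcg_amp_scale, morph_jitter = morph_jitter,
         resp_rate = resp_rate, resp_amp_scale = resp_amp_scale,
         resp_harmonic_frac = resp_harmonic_frac,
         resp_am_depth = resp_am_depth, resp_noise_frac = resp_noise_frac,
         artifact_rate = artifact_rate, noise_sd = noise_sd,
         p_unrecognizable = p_unrecognizable),
    class = "bcg_class_params"
  )
}

#' @rdname class_params
#' @export
nonhf_class_params <- function() class_params()

#' @rdname class_params
#' @export
hf_class_params <- function() {
  class_params(mean_hr = 80, hr_jitter_cv = 0.15, bcg_amp_scale = 0.5,
               morph_jitter = 0.3, resp_rate = 22, resp_amp_scale = 1.3,
               resp_harmonic_frac = 0.1, resp_am_depth = 0.08,
               resp_noise_frac = 0.03, artifact_rate = 0.5, noise_sd = 10,
               p_unrecognizable = 0.4)
}

#' Generate a clean BCG beat train
#'
#' Places jittered copies of a beat template at onsets drawn with mean
#' period `60 / mean_hr` and beat-to-beat coefficient of variation
#' `hr_jitter_cv` (periods are floored at the template duration so complexes
#' stay resolvable). Deterministic for a fixed seed.
#'
#' @param template A [beat_template()].
#' @param params A [class_params()] bundle.
#' @param duration Signal duration (s).
#' @param fs Sampling rate (Hz); must exceed twice the 8.5 Hz band edge.
#' @param seed Integer RNG seed.
#' @return A list with `signal` (numeric, model units) and `onsets`
#'   (beat onset times, s).
#' @examples
#' bt <- make_beat_train(beat_template(), class_params(), 10, 100, seed = 1)
#' length(bt$onsets)
#' @export
make_beat_train <- function(template, params, duration, fs, seed = 1) {
  stopifnot_positive(duration, "duration")
  stopifnot_positive(fs, "fs")
  if (fs <= 2 * 8.5) {
    abort("fs must exceed twice the 8.5 Hz BCG band edge",
          class = "bcghf_invalid_argument")
  }
  mean_period <- 60 / params$mean_hr
  min_period <- max(beat_duration(template), 0.3 * mean_period)
  n <- round(duration * fs)
  tgrid <- seq_len(n) / fs

  with_seed(seed, {
    # onset times: cumulative jittered periods, floored at min_period.
    # Periods follow an AR(1) sequence (lag-1 correlation 0.9) with the
    # requested marginal CV: heart-rate variability is dominated by slow
    # autonomic modulation, not white beat-to-beat noise.
    n_max <- ceiling(duration / mean_period * 2) + 10L
    phi <- 0.9
    sdev <- params$hr_jitter_cv * mean_period
    dev <- numeric(n_max)
    dev[1] <- rnorm(1, 0, sdev)
    innov <- rnorm(n_max, 0, sdev * sqrt(1 - phi^2))
    for (k in 2:n_max) dev[k] <- phi * dev[k - 1] + innov[k]
    periods <- pmax(mean_period + dev, min_period)
    onsets <- c(0, cumsum(periods))
    onsets <- onsets[onsets < duration]

    sig <- numeric(n)
    span <- beat_duration(template)
    nw <- length(template$wave_amplitudes)
    for (ons in onsets) {
      af <- if (params$morph_jitter > 0) {
        pmax(rnorm(nw, 1, params$morph_jitter), 0.1)
      } else NULL
      wf <- if (params$morph_jitter > 0) {
        max(rnorm(1, 1, params$morph_jitter / 2), 0.4)
      } else 1
      i0 <- max(1L, floor(ons * fs) + 1L)
      i1 <- min(n, ceiling((ons + span) * fs) + 1L)
      if (i0 > n) next
      idx <- i0:i1
      sig[idx] <- sig[idx] +
        eval_template(template, tgrid[idx] - ons, af, wf)
    }
    list(signal = params$bcg_amp_scale * sig, onsets = onsets)
  })
}

#' Generate a clean respiratory effort signal
#'
#' A quasi-sinusoid at `resp_rate / 60` Hz with a stated fraction of
#' second-harmonic energy, slow (~0.015 Hz) amplitude modulation, and a
#' fine-scale stochastic effort component band-limited below 1 Hz; all
#' spectral energy lies below 1 Hz for physiological breathing rates. The
#' stochastic fraction encodes breath-to-breath irregularity, which is
#' large in healthy breathing and small in the stereotyped dyspneic
#' breathing of heart failure.
#'
#' @inheritParams make_beat_train
#' @return Numeric respiratory signal in model units.
#' @examples
#' r <- make_respiration(class_params(resp_rate = 15), 60, 100, seed = 1)
#' @export
make_respiration <- function(params, duration, fs, seed = 1) {
  stopifnot_positive(duration, "duration")
  stopifnot_positive(fs, "fs")
  f <- params$resp_rate / 60
  h <- params$resp_harmonic_frac
  n <- round(duration * fs)
  tt <- seq_len(n) / fs
  with_seed(seed, {
    ph1 <- runif(1, 0, 2 * pi)
    ph2 <- runif(1, 0, 2 * pi)
    pham <- runif(1, 0, 2 * pi)
    am <- 1 + params$resp_am_depth * sin(2 * pi * 0.015 * tt + pham)
    wave <- am * (sqrt(1 - h) * sin(2 * pi * f * tt + ph1) +
                    sqrt(h) * sin(4 * pi * f * tt + ph2))
    if (params$resp_noise_frac > 0) {
      lp <- signal::butter(4, min(1 / (fs / 2), 0.99))
      nz <- filtfilt_pad(lp, rnorm(n))
      wave <- wave + params$resp_noise_frac * (sd(wave) / sd(nz)) * nz
    }
    params$resp_amp_scale * wave
  })
}

new_recording <- function(time_s, counts, fs, subject_id, label, meta = list()) {
  out <- tibble(time_s = time_s, counts = counts)
  attr(out, "fs") <- fs
  attr(out, "subject_id") <- subject_id
  attr(out, "label") <- label
  attr(out, "meta") <- meta
  class(out) <- c("bcg_recording", class(out))
  out
}

#' @export
print.bcg_recording <- function(x, ...) {
  cat(sprintf("<bcg_recording> subject %s, label %s, %.1f s @ %g Hz\n",
              attr(x, "subject_id"), format(attr(x, "label")),
              nrow(x) / attr(x, "fs"), attr(x, "fs")))
  NextMethod()
}

#' Accessors for recording metadata
#' @param rec A `bcg_recording`.
#' @return The sampling rate, subject id, label or meta list.
#' @export
recording_fs <- function(rec) attr(rec, "fs")

#' @rdname recording_fs
#' @export
recording_subject <- function(rec) attr(rec, "subject_id")

#' @rdname recording_fs
#' @export
recording_label <- function(rec) attr(rec, "label")

#' @rdname recording_fs
#' @export
recording_meta <- function(rec) attr(rec, "meta")

#' Generate a digitised force-sensor recording with ground truth
#'
#' Mixes a BCG beat train, respiratory effort, slow baseline drift
#' (sinusoids below 0.05 Hz), Poisson-placed 0.3-s raised-cosine artifact
#' spikes of 5-10 times the BCG amplitude, and white sensor noise; applies a
#' fixed gain of 150 counts per model unit and quantises to signed
#' `adc_bits` integers (clipping sets a warning flag in the metadata).
#' With probability `p_unrecognizable` each 30-s block's BCG component is
#' attenuated to an unrecognizable level, emulating HF patients whose
#' heartbeat cannot be located in the BCG.
#'
#' @inheritParams make_beat_train
#' @param subject_id Subject identifier.
#' @param label Binary class label (1 = HF, 0 = non-HF).
#' @param adc_bits ADC resolution in bits (>= 8).
#' @param template Beat template; defaults to [beat_template()].
#' @return A list with `recording` (a `bcg_recording` tibble of
#'   `time_s`/`counts`) and `truth` (clean components in counts, beat onsets,
#'   artifact mask, drift, and the per-epoch degradation indicator).
#' @examples
#' r <- make_recording(class_params(), "S1", 0, duration = 30, fs = 200, seed = 1)
#' names(r$truth)
#' @export
make_recording <- function(params, subject_id, label, duration = 30, fs = 1000,
                           adc_bits = 12, seed = 1,
                           template = beat_template()) {
  stopifnot_positive(duration, "duration")
  stopifnot_positive(fs, "fs")
  if (adc_bits < 8) {
    abort("adc_bits must be >= 8", class = "bcghf_invalid_argument")
  }
  seeds <- derive_seeds(seed, 5)
  n <- round(duration * fs)
  tt <- seq_len(n) / fs

  bt <- make_beat_train(template, params, duration, fs, seeds[1])
  bcg <- bt$signal
  res <- make_respiration(params, duration, fs, seeds[2])

  # per-30-s-block BCG degradation (unrecognizable heartbeat): disordered
  # cardiac micro-motion replaces most of the coherent beat train - the
  # residual beats are attenuated to 8% and incoherent 2-8.5 Hz noise of
  # comparable energy is added, so the block keeps cardiac-band power but
  # loses beat periodicity.
  n_blocks <- max(1L, floor(duration / 30))
  degraded <- with_seed(seeds[3], runif(n_blocks) < params$p_unrecognizable)
  if (any(degraded)) {
    rms_coh <- sqrt(mean(bcg^2))
    incoh <- with_seed(seeds[3] %% 100000L + 7L, {
      bp <- signal::butter(4, c(2, 8.5) / (fs / 2), type = "pass")
      z <- filtfilt_pad(bp, rnorm(n))
      z * (0.6 * rms_coh) / sqrt(mean(z^2))
    })
    gain_t <- rep(1, n)
    ramp <- round(0.5 * fs)
    for (b in which(degraded)) {
      i0 <- (b - 1L) * 30L * fs + 1L
      i1 <- if (b == n_blocks) n else b * 30L * fs
      gain_t[i0:i1] <- 0.08
      # half-cosine ramps so degradation does not introduce steps
      if (i0 > 1L) {
        k <- min(ramp, i0 - 1L)
        gain_t[(i0 - k):(i0 - 1L)] <-
          pmin(gain_t[(i0 - k):(i0 - 1L)],
               0.08 + 0.92 * (1 - cos(pi * (k:1) / k)) / 2)
      }
      if (i1 < n) {
        k <- min(ramp, n - i1)
        gain_t[(i1 + 1L):(i1 + k)] <-
          pmin(gain_t[(i1 + 1L):(i1 + k)],
               0.08 + 0.92 * (1 - cos(pi * (1:k) / k)) / 2)
      }
    }
    bcg <- bcg * gain_t + incoh * (1 - gain_t) / 0.92
  }

  drift <- with_seed(seeds[4], {
    f <- runif(3, 0.005, 0.045)
    ph <- runif(3, 0, 2 * pi)
    a <- c(0.10, 0.07, 0.05)
    a[1] * sin(2 * pi * f[1] * tt + ph[1]) +
      a[2] * sin(2 * pi * f[2] * tt + ph[2]) +
      a[3] * sin(2 * pi * f[3] * tt + ph[3])
  })

  spikes <- numeric(n)
  artifact_mask <- logical(n)
  with_seed(seeds[5], {
    n_spikes <- rpois(1, params$artifact_rate * duration / 60)
    if (n_spikes > 0) {
      starts <- runif(n_spikes, 0, max(duration - 0.3, 0))
      amps <- runif(n_spikes, 5, 10) * params$bcg_amp_scale *
        sample(c(-1, 1), n_spikes, replace = TRUE)
      w <- round(0.3 * fs)
      for (s in seq_len(n_spikes)) {
        i0 <- floor(starts[s] * fs) + 1L
        idx <- i0:min(n, i0 + w - 1L)
        shape <- (1 - cos(2 * pi * seq_along(idx) / length(idx))) / 2
        spikes[idx] <- spikes[idx] + amps[s] * shape
        artifact_mask[idx] <- TRUE
      }
    }
    noise <- rnorm(n, 0, params$noise_sd) # counts
    mix <- .ADC_GAIN * (bcg + res + drift + spikes) + noise
    lim <- 2^(adc_bits - 1)
    q <- round(mix)
    clipped <- any(q < -lim | q > lim - 1)
    if (clipped) q <- pmin(pmax(q, -lim), lim - 1)
    rec <- new_recording(tt, as.integer(q), fs, subject_id, label,
                         meta = list(seed = seed, adc_bits = adc_bits,
                                     clipped = clipped))
    truth <- list(bcg_true = .ADC_GAIN * bcg, res_true = .ADC_GAIN * res,
                  drift_true = .ADC_GAIN * drift,
                  beat_onsets = bt$onsets, artifact_mask_true = artifact_mask,
                  epochs_degraded = degraded)
    list(recording = rec, truth = truth)
  })
}

# perturb one subject's parameters around the class means (10% CV, clamped)
perturb_params <- function(params, cv = 0.1) {
  fields <- c("mean_hr", "hr_jitter_cv", "bcg_amp_scale", "morph_jitter",
              "resp_rate", "resp_amp_scale", "artifact_rate", "noise_sd")
  for (f in fields) {
    fac <- min(max(rnorm(1, 1, cv), 1 - 3 * cv), 1 + 3 * cv)
    params[[f]] <- params[[f]] * fac
  }
  class(params) <- "bcg_class_params"
  params
}

#' Generate a labelled synthetic cohort
#'
#' Each subject contributes `epochs_per_subject` x 30 s of signal; subject
#' parameters are drawn around the class means with 10% coefficient of
#' variation to create between-subject variability. Fully reproducible for a
#' fixed seed.
#'
#' @param n_hf,n_nonhf Number of HF and non-HF subjects (>= 1).
#' @param epochs_per_subject 30-s epochs of signal generated per subject.
#' @param hf_params,nonhf_params Class parameter bundles.
#' @param seed Integer RNG master seed.
#' @param fs Sampling rate (Hz).
#' @param adc_bits ADC resolution.
#' @param subject_cv Between-subject parameter coefficient of variation.
#' @param template Beat template shared by the cohort.
#' @return A tibble with one row per subject: `subject_id`, `label`,
#'   `seed`, and list-columns `params`, `recording`, `truth`.
#' @examples
#' coh <- make_cohort(2, 2, 1, seed = 1, fs = 200)
#' coh$subject_id
#' @export
make_cohort <- function(n_hf, n_nonhf, epochs_per_subject,
                        hf_params = hf_class_params(),
                        nonhf_params = nonhf_class_params(),
                        seed = 1, fs = 1000, adc_bits = 12, subject_cv = 0.1,
                        template = beat_template()) {
  for (nm in c("n_hf", "n_nonhf", "epochs_per_subject")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 1) {
      abort(sprintf("`%s` must be >= 1", nm), class = "bcghf_invalid_argument")
    }
  }
  n_sub <- n_hf + n_nonhf
  seeds <- derive_seeds(seed, 2 * n_sub)
  labels <- c(rep(1L, n_hf), rep(0L, n_nonhf))
  ids <- c(sprintf("HF%02d", seq_len(n_hf)), sprintf("NH%02d", seq_len(n_nonhf)))
  duration <- epochs_per_subject * 30

  rows <- purrr::map(seq_len(n_sub), function(i) {
    base <- if (labels[i] == 1L) hf_params else nonhf_params
    pars <- with_seed(seeds[i], perturb_params(base, subject_cv))
    rec <- make_recording(pars, ids[i], labels[i], duration = duration,
                          fs = fs, adc_bits = adc_bits,
                          seed = seeds[n_sub + i], template = template)
    tibble(subject_id = ids[i], label = labels[i], seed = seeds[n_sub + i],
           params = list(pars), recording = list(rec$recording),
           truth = list(rec$truth))
  })
  dplyr::bind_rows(rows)
}
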