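# Synthetic generator: beat trains, respiration, recordings, cohorts.

test_that("jitter-free beat train is exactly periodic", {
  p <- class_params(mean_hr = 60, hr_jitter_cv = 0, morph_jitter = 0)
  bt <- make_beat_train(beat_template(), p, duration = 10, fs = 1000, seed = 3)
  expect_length(bt$onsets, 10)
  expect_equal(diff(bt$onsets), rep(1, 9), tolerance = 1e-3)
})

test_that("generators are deterministic in the seed and vary across seeds", {
  p <- class_params()
  a <- make_beat_train(beat_template(), p, 5, 500, seed = 7)
  b <- make_beat_train(beat_template(), p, 5, 500, seed = 7)
  expect_identical(a, b)
  c1 <- make_respiration(p, 5, 500, seed = 1)
  c2 <- make_respiration(p, 5, 500, seed = 2)
  expect_false(identical(c1, c2))
  r1 <- make_recording(p, "S", 0, 5, 500, seed = 9)
  r2 <- make_recording(p, "S", 0, 5, 500, seed = 9)
  expect_identical(r1$recording$counts, r2$recording$counts)
})

test_that("inter-onset intervals reproduce the requested CV", {
  # the AR(1) period correlation widens the sampling spread of a single
  # 300-s realization, so the moment check averages a few seeds
  p <- class_params(hr_jitter_cv = 0.15)
  cvs <- sapply(1:5, function(s) {
    bt <- make_beat_train(beat_template(), p, duration = 300, fs = 200,
                          seed = s)
    iv <- diff(bt$onsets)
    expect_gt(length(iv), 200)
    sd(iv) / mean(iv)
  })
  expect_lt(abs(mean(cvs) - 0.15), 0.03)
})

test_that("respiration has the constructed spectral properties", {
  fs <- 100
  p <- class_params(resp_rate = 15, resp_harmonic_frac = 0)
  r <- make_respiration(p, 120, fs, seed = 2)
  n <- length(r)
  sp <- Mod(fft(r - mean(r)))^2
  freq <- (0:(n - 1)) * fs / n
  peak <- freq[which.max(sp[2:(n %/% 2)]) + 1]
  expect_equal(peak, 0.25, tolerance = fs / n + 1e-9)
  # harmonic-free deterministic waveform: THD below 1%
  pd <- class_params(resp_rate = 15, resp_harmonic_frac = 0,
                     resp_noise_frac = 0)
  rd <- make_respiration(pd, 120, fs, seed = 2)
  spd <- Mod(fft(rd - mean(rd)))^2
  f0 <- 15 / 60
  harm <- sapply(2:4, function(k) sum(spd[abs(freq - k * f0) < 0.02]))
  expect_lt(sum(harm) / sum(spd[2:(n %/% 2)]), 0.01)
  # amplitude linearity at fixed seed
  p2 <- class_params(resp_rate = 15, resp_harmonic_frac = 0,
                     resp_amp_scale = 2 * p$resp_amp_scale)
  r2 <- make_respiration(p2, 120, fs, seed = 2)
  expect_equal(sqrt(mean(r2^2)) / sqrt(mean(r^2)), 2, tolerance = 0.01)
})

test_that("digitisation adds at most half an ADC step of error", {
  p <- class_params(noise_sd = 0, artifact_rate = 0)
  r <- make_recording(p, "S", 0, duration = 30, fs = 500, seed = 6)
  clean <- r$truth$bcg_true + r$truth$res_true + r$truth$drift_true
  err <- r$recording$counts - clean
  expect_lte(max(abs(err)), 0.5 + 1e-9)
  expect_lte(length(unique(r$recording$counts)), 2^12)
})

test_that("artifact spikes follow the requested Poisson rate", {
  counts <- sapply(1:50, function(s) {
    p <- class_params(artifact_rate = 6, noise_sd = 0)
    r <- make_recording(p, "S", 0, duration = 60, fs = 100, seed = 100 + s)
    rl <- rle(r$truth$artifact_mask_true)
    sum(rl$values)
  })
  # mean of 50 Poisson(6) draws: 99% interval for the sample mean
  expect_gt(mean(counts), 6 - 2.58 * sqrt(6 / 50))
  expect_lt(mean(counts), 6 + 2.58 * sqrt(6 / 50))
})

test_that("spectral separation of the ground-truth components holds", {
  energy_frac <- function(x, fs, lo, hi) {
    n <- length(x)
    sp <- Mod(fft(x - mean(x)))^2
    freq <- (0:(n - 1)) * fs / n
    half <- 2:(n %/% 2)
    sum(sp[half][freq[half] >= lo & freq[half] <= hi]) / sum(sp[half])
  }
  for (p in list(class_params(), hf_class_params())) {
    bt <- make_beat_train(beat_template(), p, 60, 1000, seed = 1)
    expect_gte(energy_frac(bt$signal, 1000, 2, 8.5), 0.90)
    r <- make_respiration(p, 60, 1000, seed = 1)
    expect_gte(energy_frac(r, 1000, 0, 1), 0.95)
  }
})

test_that("class contrasts point the expected way", {
  coh <- small_cohort()
  amp <- sapply(coh$truth, function(tr) sqrt(mean(tr$bcg_true^2)))
  ratio <- sapply(coh$truth, function(tr) {
    mean(tr$res_true^2) / mean(tr$bcg_true^2)
  })
  hf <- coh$label == 1
  expect_lt(mean(amp[hf]), mean(amp[!hf]))
  expect_gt(mean(ratio[hf]), mean(ratio[!hf]))
})

test_that("HF breathing is intrinsically more stereotyped than healthy breathing", {
  fe_l <- function(x) {
    xd <- bcghf:::decimate_signal(x, 1000, 10)
    mean(fe_series(xd, window_spec(6, 1, 10, length(xd))))
  }
  nh <- sapply(1:8, function(s) fe_l(make_respiration(class_params(), 30, 1000, seed = s)))
  hf <- sapply(1:8, function(s) fe_l(make_respiration(hf_class_params(), 30, 1000, seed = 100 + s)))
  expect_lt(median(hf), median(nh))
})

test_that("cohorts have the requested size, balance and reproducibility", {
  coh <- make_cohort(3, 2, 4, seed = 2, fs = 100)
  expect_equal(nrow(coh), 5)
  expect_equal(sum(coh$label == 1), 3)
  expect_equal(sum(coh$label == 0), 2)
  secs <- sapply(coh$recording, function(r) nrow(r) / recording_fs(r))
  expect_equal(secs, rep(4 * 30, 5))
  coh2 <- make_cohort(3, 2, 4, seed = 2, fs = 100)
  expect_identical(coh$recording[[1]]$counts, coh2$recording[[1]]$counts)
  coh3 <- make_cohort(3, 2, 4, seed = 3, fs = 100)
  expect_false(identical(coh$recording[[1]]$counts, coh3$recording[[1]]$counts))
})

test_that("invalid generator arguments are rejected", {
  expect_error(make_beat_train(beat_template(), class_params(), -1, 100),
               class = "bcghf_invalid_argument")
  expect_error(make_beat_train(beat_template(), class_params(), 10, 10),
               class = "bcghf_invalid_argument")
  expect_error(class_params(resp_harmonic_frac = 1.5),
               class = "bcghf_invalid_argument")
  expect_error(make_recording(class_params(), "S", 0, adc_bits = 4, seed = 1),
               class = "bcghf_invalid_argument")
  expect_error(beat_template(carrier_freq = 9),
               class = "bcghf_invalid_argument")
})
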