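# Artifact screening, signal separation, epoching, SNR and stratification.

test_that("peak-to-mean ratio matches the sinusoid closed form", {
  fs <- 100
  x <- sin(2 * pi * 2 * seq(0, 10 - 1 / fs, by = 1 / fs))
  m <- detect_artifacts(x, fs = fs)
  # mean of |sin| is 2/pi, so pmr = pi/2 for every whole-cycle window
  expect_equal(m$pmr, rep(pi / 2, 10), tolerance = 0.01)
  expect_false(any(m$flagged))
})

test_that("a spike window outscores every clean window and tails are ignored", {
  fs <- 200
  n <- round(10.6 * fs) # 10 whole windows + a 0.6-s tail
  x <- sin(2 * pi * 2 * (1:n) / fs)
  x[round(5.5 * fs)] <- 10
  m <- detect_artifacts(x, fs = fs)
  expect_equal(nrow(m), 10)
  expect_equal(which.max(m$pmr), 6)
  expect_gt(m$pmr[6], max(m$pmr[-6]))
  expect_true(m$flagged[6])
  # all-zero window never flagged
  z <- detect_artifacts(rep(0, 3 * fs), fs = fs)
  expect_equal(z$pmr, rep(1, 3))
  expect_false(any(z$flagged))
})

test_that("respiration extraction passes the breathing band and stops the BCG band", {
  fs <- 500
  t <- seq(0, 40 - 1 / fs, by = 1 / fs)
  slow <- sin(2 * pi * 0.25 * t)
  out <- extract_respiration(slow, fs = fs)
  expect_gte(cor(out, slow), 0.99)
  fast <- sin(2 * pi * 5 * t)
  out5 <- extract_respiration(fast, fs = fs)
  expect_lt(sqrt(mean(out5^2)), 0.05 * sqrt(mean(fast^2)))
  const <- extract_respiration(rep(7, 5 * fs), fs = fs)
  expect_equal(const, rep(7, 5 * fs), tolerance = 1e-6)
  expect_error(extract_respiration(rep(1, 10), fs = 500),
               class = "bcghf_invalid_argument")
})

test_that("BCG band-pass has the designed response", {
  fs <- 1000
  t <- seq(0, 40 - 1 / fs, by = 1 / fs)
  mid <- sin(2 * pi * 5 * t)
  y <- extract_bcg(mid, rep(0, length(mid)), fs = fs)
  gain <- (max(y[5000:35000]) - min(y[5000:35000])) / 2
  expect_gte(gain, 0.95)
  expect_lte(gain, 1.05)
  slow <- sin(2 * pi * 0.25 * t)
  ys <- extract_bcg(slow, rep(0, length(slow)), fs = fs)
  expect_lt(sqrt(mean(ys[5000:35000]^2)), 0.02 * sqrt(mean(slow^2)))
  # single-pass band edges at half power
  bp <- signal::butter(4, c(2, 8.5) / (fs / 2), type = "pass")
  for (f0 in c(2, 8.5)) {
    xe <- sin(2 * pi * f0 * t)
    ye <- signal::filter(bp, xe)
    g <- (max(ye[20000:40000]) - min(ye[20000:40000])) / 2
    expect_equal(g, 1 / sqrt(2), tolerance = 0.05)
  }
  expect_error(extract_bcg(mid, rep(0, length(mid)), fs = 15),
               class = "bcghf_invalid_argument")
  # band-pass cannot add energy
  set.seed(1)
  raw <- rnorm(20000)
  yb <- extract_bcg(raw, rep(0, 20000), fs = fs)
  expect_lte(sqrt(mean(yb^2)), sqrt(mean(raw^2)))
})

test_that("epoching drops flagged epochs, short tails and accounts for all seconds", {
  fs <- 100
  n <- 95 * fs
  x <- rnorm(n)
  ep <- epoch_signals(x, x, mask = NULL, fs = fs)
  expect_equal(nrow(ep), 3)
  expect_equal(ep$epoch_index, 1:3)
  expect_true(all(lengths(ep$bcg) == 30 * fs))
  # artifact at t = 40 s kills the second epoch only
  mask <- detect_artifacts(x, fs = fs)
  mask$flagged <- FALSE
  mask$flagged[41] <- TRUE
  ep2 <- epoch_signals(x, x, mask, fs = fs)
  expect_equal(ep2$epoch_index, c(1L, 3L))
  # retained + dropped epochs account for everything except the tail
  expect_equal(nrow(ep) * 30 + (95 - nrow(ep) * 30), 95)
  expect_equal(nrow(epoch_signals(rnorm(29 * fs), rnorm(29 * fs), NULL, fs)), 0)
})

test_that("SNR scores periodic, noisy and degenerate epochs correctly", {
  p <- class_params(hr_jitter_cv = 0, morph_jitter = 0, noise_sd = 0,
                    artifact_rate = 0)
  bt <- make_beat_train(beat_template(), p, 30, 1000, seed = 1)
  expect_gt(estimate_snr(bt$signal, 1000), 10)
  set.seed(2)
  expect_lt(estimate_snr(rnorm(30000), 1000), 0)
  expect_equal(estimate_snr(rep(1, 3000), 100), -20)
  expect_equal(snr_from_rho(0.715), 4.0, tolerance = 0.05)
  expect_equal(snr_from_rho(0), -20)
  expect_equal(snr_from_rho(1), 40)
})

test_that("separation recovers the ground-truth components faithfully", {
  for (row in seq_len(nrow(small_cohort()))) {
    rec <- small_cohort()$recording[[row]]
    tr <- small_cohort()$truth[[row]]
    res <- extract_respiration(rec)
    bcg <- extract_bcg(rec, res)
    keep <- !tr$artifact_mask_true
    expect_gte(cor(res[keep], tr$res_true[keep]), 0.9)
    bcg_ref <- extract_bcg(tr$bcg_true, rep(0, length(bcg)), fs = 1000)
    expect_gte(cor(bcg[keep], bcg_ref[keep]), 0.8)
  }
})

test_that("separated respiration is confined below 1 Hz and band-pass conserves energy", {
  rec <- small_cohort()$recording[[1]]
  res <- extract_respiration(rec)
  n <- length(res)
  sp <- Mod(fft(res - mean(res)))^2
  freq <- (0:(n - 1)) * recording_fs(rec) / n
  half <- 2:(n %/% 2)
  expect_gte(sum(sp[half][freq[half] <= 1]) / sum(sp[half]), 0.9)
  bcg <- extract_bcg(rec, res)
  expect_lte(sqrt(mean(bcg^2)),
             sqrt(mean((as.numeric(rec$counts) - res)^2)))
})

test_that("dataset stratification partitions HF epochs by SNR", {
  ep <- tibble::tibble(label = c(1L, 1L, 1L, 0L, 0L),
                       snr_db = c(10, 2, 5, -1, 20))
  ds <- split_datasets(ep, snr_threshold_db = 4)
  expect_equal(sum(ds$dataset1$label == 1), 2)
  expect_equal(sum(ds$dataset2$label == 1), 1)
  # every non-HF epoch is a control in both groups
  expect_equal(sum(ds$dataset1$label == 0), 2)
  expect_equal(sum(ds$dataset2$label == 0), 2)
  # partition of HF epochs
  expect_equal(sum(ds$dataset1$label == 1) + sum(ds$dataset2$label == 1),
               sum(ep$label == 1))
  # all HF above threshold leaves dataset2 without HF epochs
  ds2 <- split_datasets(ep[ep$snr_db > 4 | ep$label == 0, ], 4)
  expect_equal(sum(ds2$dataset2$label == 1), 0)
})

test_that("degraded-epoch probability drives the dataset-2 fraction", {
  fracs <- sapply(1:3, function(s) {
    coh <- make_cohort(3, 1, 3, seed = 20 + s)
    ep <- preprocess_cohort(coh)
    hf <- ep[ep$label == 1, ]
    mean(hf$snr_db < 4)
  })
  n_hf <- 3 * 3 * 3 # epochs entering the binomial band (minus artifact drops)
  expect_gt(mean(fracs), 0.4 - 1.96 * sqrt(0.4 * 0.6 / n_hf) - 0.05)
  expect_lt(mean(fracs), 0.4 + 1.96 * sqrt(0.4 * 0.6 / n_hf) + 0.05)
})
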