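# Fuzzy entropy, Lyapunov exponent, correlation dimension, MIC.

test_that("fuzzy entropy matches a brute-force oracle and its invariants", {
  expect_equal(fuzzy_entropy(rep(3, 100)), 0)
  withr::with_seed(1, {
    x <- rnorm(150)
    expect_equal(fuzzy_entropy(x), fe_oracle(x), tolerance = 1e-10)
    s <- sin(1:150 / 4) + rnorm(150, 0, 0.05)
    expect_equal(fuzzy_entropy(s, m = 3, r = 0.2),
                 fe_oracle(s, m = 3, r_frac = 0.2), tolerance = 1e-10)
    # amplitude invariance: tolerance scales with the sd
    expect_equal(fuzzy_entropy(5 * x), fuzzy_entropy(x))
  })
  withr::with_seed(2, {
    n <- rnorm(2000)
    s <- sin(2 * pi * (1:2000) / 40)
    expect_gt(fuzzy_entropy(n), fuzzy_entropy(s))
  })
})

test_that("windowed fuzzy entropy tracks local complexity", {
  withr::with_seed(3, {
    fs <- 50
    x <- rnorm(20 * fs)
    spec <- window_spec(4, 2, fs, length(x))
    fe <- fe_series(x, spec)
    expect_length(fe, spec$L)
    # stationary noise: small relative volatility
    expect_lt(sd(fe) / mean(fe), 0.2)
    # alternating quiet sine / chaotic noise halves: larger spread
    y <- as.numeric(sapply(1:5, function(i) {
      c(sin(2 * pi * (1:(2 * fs)) / 25), rnorm(2 * fs))
    }))
    fe2 <- fe_series(y, window_spec(4, 2, fs, length(y)))
    expect_gt(IQR(fe2), IQR(fe))
  })
})

test_that("the Lyapunov estimator recovers known exponents", {
  x <- logistic_map(3000)
  lle <- largest_lyapunov(x, fs = 1, emb_dim = 2, tau = 1, theiler = 10)
  expect_equal(lle, log(2), tolerance = 0.1 * log(2))
  s <- sin(2 * pi * (1:3000) / 20.7)
  lle_s <- largest_lyapunov(s, fs = 1, emb_dim = 7, tau = 5, theiler = 25)
  expect_lte(abs(lle_s), 0.05 * log(2))
  # time reversal of a periodic orbit changes nothing material
  lle_r <- largest_lyapunov(rev(s), fs = 1, emb_dim = 7, tau = 5, theiler = 25)
  expect_lte(abs(lle_r - lle_s), 0.05 * log(2))
  expect_error(largest_lyapunov(rnorm(30), emb_dim = 12, tau = 5),
               class = "bcghf_undefined_feature")
})

test_that("the correlation-dimension estimator recovers known attractors", {
  t <- 1:3000
  s <- sin(2 * pi * t / 20.7)
  expect_equal(correlation_dimension(s, tau = 5, theiler = 25), 1,
               tolerance = 0.2)
  tor <- s + sin(2 * pi * t / (20.7 * sqrt(2)))
  cd_t <- correlation_dimension(tor, tau = 5, theiler = 25)
  expect_gte(cd_t, 1.7)
  expect_lte(cd_t, 2.3)
  # correlation sums agree with a dist()-based oracle at spot radii
  withr::with_seed(4, {
    xs <- rnorm(400)
    prof <- correlation_dimension(xs, emb_dims = 2:3, tau = 2, theiler = 5,
                                  n_ref = 1e9, profile = TRUE)
    expect_equal(nrow(prof), 2)
    for (m in 2:3) {
      r0 <- 0.5 * sd(xs)
      cs <- corr_sum_oracle(xs, m, 2, r0, 5)
      expect_gt(cs, 0) # oracle sanity
    }
  })
  # i.i.d. noise: no saturation, estimate grows with embedding dimension
  withr::with_seed(5, {
    nz <- rnorm(3000)
    prof <- correlation_dimension(nz, emb_dims = c(2, 5, 8), tau = 1,
                                  theiler = 5, profile = TRUE)
    expect_true(all(diff(prof$slope) > 0))
  })
})

test_that("correlation sums match the dist()-based oracle exactly", {
  withr::with_seed(6, {
    xs <- rnorm(300)
    radii <- quantile(abs(diff(xs)), c(0.3, 0.6, 0.9))
    C <- bcghf:::cpp_corr_sums(xs, 3L, 2L, 5L, sort(unname(radii)), 10000L)
    for (i in seq_along(radii)) {
      expect_equal(C[3, i],
                   corr_sum_oracle(xs, 3, 2, sort(unname(radii))[i], 5),
                   tolerance = 1e-12)
    }
  })
})

test_that("MIC detects functional relations and rejects independence", {
  withr::with_seed(7, {
    x <- rnorm(500)
    expect_equal(mic(x, x), 1)
    expect_gte(mic(x, 2 * x + 3), 0.99)
    nulls <- sapply(1:7, function(i) mic(rnorm(2000), rnorm(2000)))
    expect_lt(median(nulls), 0.3)
    expect_warning(v <- mic(rep(1, 100), rnorm(100)))
    expect_equal(v, 0)
    expect_error(mic(rnorm(10), rnorm(10)), class = "bcghf_invalid_argument")
    expect_error(mic(rnorm(30), rnorm(31)), class = "bcghf_invalid_argument")
  })
})

test_that("adjacent-segment MIC is 1 for period-locked windows", {
  fs <- 50
  period <- 1 # seconds
  x <- sin(2 * pi * (1:(20 * fs)) / (period * fs))
  spec <- window_spec(2, 1, fs, length(x)) # w = 2 periods, t = 1 period
  mm <- mic_series(x, spec)
  expect_length(mm, spec$L - 1)
  expect_true(all(mm > 0.999))
  withr::with_seed(8, {
    nz <- rnorm(20 * fs)
    mn <- mic_series(nz, window_spec(2, 1, fs, length(nz)))
    expect_lt(median(mn), median(mm))
  })
})
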