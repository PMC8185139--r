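test_that("segmentation follows the trailing-discard rule", {
  spec <- default_group_specs()$control
  rec <- simulate_eeg(spec, n_channels = 8, duration_s = 360, seed = 1)
  segs <- segment_recording(rec, window_s = 4)
  expect_length(segs, 90)
  expect_equal(dim(segs[[1]]$data), c(8, 1024))
  expect_equal(vapply(segs, `[[`, 0L, "index"), 0:89)

  rec8 <- simulate_eeg(spec, duration_s = 8, seed = 1)
  expect_length(segment_recording(rec8, 4), 2)
  rec39 <- simulate_eeg(spec, duration_s = 3.9, seed = 1)
  expect_warning(segs0 <- segment_recording(rec39, 4), "shorter")
  expect_length(segs0, 0)
  expect_error(segment_recording(rec8, 4, overlap_s = 4), "overlap")
  # half-overlap doubles the count (minus the edge)
  expect_length(segment_recording(rec8, 4, overlap_s = 2), 3)
})

test_that("approximate entropy matches the brute-force oracle", {
  withr::with_seed(42, x <- runif(100))
  r <- 0.2 * sd(x)
  expect_equal(approximate_entropy(x, 2, r), oracle_apen(x, 2, r),
               tolerance = 1e-10)
  withr::with_seed(1, y <- rnorm(150))
  expect_equal(approximate_entropy(y, 3, 0.25 * sd(y)),
               oracle_apen(y, 3, 0.25 * sd(y)), tolerance = 1e-10)
  expect_equal(approximate_entropy(rep(2.5, 60), 2, 0.1), 0)
})

test_that("white noise is less regular than a sine by approximate entropy", {
  tt <- seq_len(512) / 256
  apen_noise <- vapply(1:10, function(s) {
    withr::with_seed(s, x <- rnorm(512))
    approximate_entropy(x, 2, 0.2 * sd(x))
  }, numeric(1))
  sine <- sin(2 * pi * 10 * tt)
  expect_gt(min(apen_noise), approximate_entropy(sine, 2, 0.2 * sd(sine)))
})

test_that("sample entropy matches the brute-force oracle and its edge cases", {
  withr::with_seed(7, x <- rnorm(50))
  r <- 0.2 * sd(x)
  expect_equal(sample_entropy(x, 2, r), oracle_sampen(x, 2, r),
               tolerance = 1e-10)
  withr::with_seed(8, y <- runif(120))
  expect_equal(sample_entropy(y, 2, 0.15 * sd(y)),
               oracle_sampen(y, 2, 0.15 * sd(y)), tolerance = 1e-10)
  # strict periodicity and constancy give 0, not a degenerate sentinel
  expect_equal(sample_entropy(rep(c(1, 2, 3), 20), 2, 0.01), 0)
  expect_equal(sample_entropy(rep(1, 40), 2, 0.1), 0)
  # no (m+1)-matches at all -> documented finite cap, never NaN/Inf
  x_nomatch <- c(0, 1e3, 2, 1e6, 4, 1e9, 6, 1e12, 8, 1e15)
  val <- sample_entropy(x_nomatch, 2, 0.5)
  expect_true(is.finite(val))
})

test_that("ApEn and SampEn with relative tolerance are affine-invariant", {
  withr::with_seed(11, x <- rnorm(200))
  for (f in list(approximate_entropy, sample_entropy)) {
    a <- f(x, 2, 0.2 * sd(x))
    y <- 3.7 * x + 11
    b <- f(y, 2, 0.2 * sd(y))
    expect_equal(a, b, tolerance = 1e-10)
  }
})

test_that("permutation entropy reproduces the hand-enumerated example", {
  # [4,7,9,10,6,11,3], order 2: patterns up,up,up,down,up,down -> 4:2
  h <- -(4 / 6 * log(4 / 6) + 2 / 6 * log(2 / 6)) / log(2)
  expect_equal(permutation_entropy(c(4, 7, 9, 10, 6, 11, 3), 2, 1), h,
               tolerance = 1e-12)
  expect_equal(h, 0.9182958, tolerance = 1e-6)
  expect_equal(permutation_entropy(1:50, 3, 1), 0)
  # all 2 patterns of order 2 equally often -> maximal entropy 1
  expect_equal(permutation_entropy(rep_len(c(0, 1), 41), 2, 1), 1)
})

test_that("permutation entropy stays in [0,1] and handles ties and delays", {
  for (s in 1:20) {
    withr::with_seed(s, x <- sample(1:10, 60, replace = TRUE))  # many ties
    pe <- permutation_entropy(x, 3, 1)
    expect_gte(pe, 0); expect_lte(pe, 1)
  }
  withr::with_seed(2, x <- rnorm(100))
  expect_gte(permutation_entropy(x, 4, 2), 0)
  expect_error(permutation_entropy(c(1, 2), 3, 1), "too short")
  # ties broken by order of appearance: a constant series is one pattern
  expect_equal(permutation_entropy(rep(5, 30), 3, 1), 0)
})

test_that("wavelet entropy matches an explicit-matrix decomposition oracle", {
  withr::with_seed(13, x <- rnorm(256))
  flt <- gazegraph:::wavelet_filters("db4")
  en <- oracle_wavelet_energies(x, flt$h, flt$g, 5)
  p <- en / sum(en)
  expect_equal(wavelet_entropy(x, "db4", 5), -sum(p * log(p)),
               tolerance = 1e-8)
  # orthonormal pyramid preserves energy (Parseval)
  dec <- gazegraph:::dwt_periodized(x, "db4", 5)
  total <- sum(vapply(dec$details, function(d) sum(d^2), 0)) +
    sum(dec$approx^2)
  expect_equal(total, sum(x^2), tolerance = 1e-8)
})

test_that("wavelet entropy degenerates to 0 for single-band signals", {
  # alternating Haar high-pass eigen-signal: all energy in detail level 1
  x <- rep(c(1, -1), 64)
  expect_equal(wavelet_entropy(x, "haar", 5), 0)
  expect_equal(wavelet_entropy(rep(0, 128), "db4", 5), 0)
  expect_error(wavelet_entropy(rnorm(16), "db4", 5), "too short")
  # never exceeds log(levels)
  withr::with_seed(3, y <- rnorm(512))
  expect_lte(wavelet_entropy(y, "db4", 5), log(5))
})

test_that("STFT spectral entropy matches a direct windowed-DFT oracle", {
  withr::with_seed(21, x <- rnorm(512))
  seg <- make_segment(matrix(x, 1), rate_hz = 128)
  expect_equal(stft_spectral_entropy(seg, 1, 0.5),
               oracle_stft_entropy(x, 128, 1, 0.5), tolerance = 1e-8)
  # multichannel = mean of per-channel entropies
  withr::with_seed(22, m <- matrix(rnorm(1024), 2))
  seg2 <- make_segment(m, rate_hz = 128)
  expect_equal(stft_spectral_entropy(seg2, 1, 0.5),
               mean(c(oracle_stft_entropy(m[1, ], 128, 1, 0.5),
                      oracle_stft_entropy(m[2, ], 128, 1, 0.5))),
               tolerance = 1e-8)
})

test_that("STFT spectral entropy separates tones from noise", {
  tt <- seq_len(1024) / 256
  tone <- make_segment(matrix(sin(2 * pi * 10 * tt), 1), 256)
  withr::with_seed(4, noise <- make_segment(matrix(rnorm(1024), 1), 256))
  h_tone <- stft_spectral_entropy(tone)
  h_noise <- stft_spectral_entropy(noise)
  expect_lt(h_tone, h_noise)
  # white noise approaches the log of the number of (time, frequency) bins
  n_bins <- 129 * 7  # 1 s windows, 0.5 s hop on a 4 s segment at 256 Hz
  expect_gt(h_noise, 0.9 * log(n_bins))
  expect_lt(h_noise, log(n_bins))
  zero <- make_segment(matrix(0, 1, 1024), 256)
  expect_equal(stft_spectral_entropy(zero), 0)
})

test_that("PCC synchronization matches hand-computed correlations", {
  toy <- make_segment(rbind(c(1, 2, 3), c(2, 4, 6), c(3, 2, 1)), 1)
  res <- pcc_synchronization(toy)
  expect_equal(res$matrix[1, 2], 1)
  expect_equal(res$matrix[1, 3], -1)
  expect_equal(res$matrix[2, 3], -1)
  expect_equal(res$scalar, -1 / 3)
  # identical channels -> all ones
  same <- make_segment(rbind(1:5, 1:5, 1:5), 1)
  expect_equal(pcc_synchronization(same)$scalar, 1)
  # x and -x -> -1
  anti <- make_segment(rbind(c(1, 3, 2, 5), -c(1, 3, 2, 5)), 1)
  expect_equal(pcc_synchronization(anti)$matrix[1, 2], -1)
  flat <- make_segment(rbind(1:4, rep(2, 4)), 1)
  expect_error(pcc_synchronization(flat), "zero-variance")
})

test_that("PCC matrix is symmetric with unit diagonal on random segments", {
  for (s in 1:5) {
    withr::with_seed(s, m <- matrix(rnorm(8 * 64), 8))
    C <- pcc_synchronization(make_segment(m, 64))$matrix
    expect_equal(C, t(C))
    expect_equal(unname(diag(C)), rep(1, 8))
    expect_true(all(C >= -1 - 1e-12 & C <= 1 + 1e-12))
  }
})

test_that("the EEG feature set has the seven canonical names in fixed order", {
  spec <- default_group_specs()$case
  rec <- simulate_eeg(spec, duration_s = 4, seed = 2)
  seg <- segment_recording(rec, 4)[[1]]
  feats <- extract_eeg_features(seg)
  expect_equal(names(feats),
               c("mean_value", "stft_entropy", "pcc_sync", "appr_en",
                 "samp_en", "perm_en", "wavelet_en"))
  expect_true(all(is.finite(feats)))
  expect_identical(feats, extract_eeg_features(seg))
  # mean_value is the grand mean of the (channel-averaged) segment
  expect_equal(unname(feats["mean_value"]), mean(seg$data))
})

test_that("combined entropy helper agrees with the individual estimators", {
  withr::with_seed(5, x <- rnorm(300))
  r <- 0.2 * sd(x)
  both <- gazegraph:::complexity_entropies(x, 2, r)
  expect_equal(unname(both["apen"]), approximate_entropy(x, 2, r))
  expect_equal(unname(both["sampen"]), sample_entropy(x, 2, r))
})

test_that("band-pass plumbing attenuates out-of-band components", {
  tt <- seq_len(2048) / 256
  inband <- sin(2 * pi * 10 * tt)
  drift <- 5 * sin(2 * pi * 0.05 * tt)
  rec <- eeg_recording(rbind(inband + drift, inband - drift), 256)
  filt <- bandpass_filter(rec, 0.5, 45)
  mid <- 512:1536  # ignore filter edge transients
  expect_lt(sd(filt$data[1, mid] - filt$data[2, mid]) / sd(drift), 0.2)
  expect_gt(sd(filt$data[1, mid]) / sd(inband), 0.5)
})
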