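# Welch estimator: segmentation arithmetic, periodogram scaling against a
# direct-DFT oracle, Parseval identity, variance reduction.

test_that("default segmentation yields 13 segments at every study duration", {
  for (t_ms in seq(250, 2000, by = 250)) {
    n <- round(t_ms * 1024 / 1000)
    segs <- segment_signal(rnorm(n))
    expect_length(segs, 13)
    expect_equal(attr(segs, "M"), round(0.25 * n))
    expect_equal(attr(segs, "hop"), round(0.25 * round(0.25 * n)))
  }
})

test_that("segmentation arithmetic and edge cases", {
  segs <- segment_signal(1:256)
  expect_equal(segs[[1]], 1:64)
  expect_equal(segs[[2]], 17:80)                      # hop 16
  expect_equal(segs[[13]], 193:256)                   # last fully inside
  whole <- segment_signal(1:256, window_fraction = 1)
  expect_length(whole, 1)
  expect_equal(whole[[1]], 1:256)
  expect_error(segment_signal(1:256, window_fraction = 0.02), "8 samples")
  expect_error(segment_signal(1:256, step_fraction = 0.001), "hop")
})

test_that("modified periodogram matches the direct-DFT oracle", {
  set.seed(21)
  x <- rnorm(32)
  w <- tukey_window(32, 0.5)
  got <- modified_periodogram(x, w, nfft = 64, f_s = 100)
  want <- naive_periodogram(x, w, nfft = 64, fs = 100)
  expect_equal(got$power, want, tolerance = 1e-9)
  expect_equal(got$frequency, (0:32) * 100 / 64)
})

test_that("rectangular window reduces to the raw periodogram (U = 1)", {
  set.seed(22)
  x <- rnorm(64)
  pg <- modified_periodogram(x, rep(1, 64), nfft = 64, f_s = 64)
  expect_equal(pg$meta$U, 1)
  # raw periodogram: |FFT|^2 / (N fs), one-sided
  X <- fft(x)
  raw <- Mod(X[1:33])^2 / (64 * 64)
  raw[2:32] <- 2 * raw[2:32]
  expect_equal(pg$power, raw, tolerance = 1e-12)
  expect_error(modified_periodogram(x, rep(0, 64)), "all-zero")
})

test_that("integrated one-sided periodogram equals windowed-signal power (Parseval)", {
  set.seed(23)
  x <- rnorm(128)
  for (w in list(rep(1, 128), tukey_window(128, 0.5))) {
    pg <- modified_periodogram(x, w, nfft = 128, f_s = 1024)
    df <- pg$frequency[2] - pg$frequency[1]
    expect_equal(sum(pg$power) * df, sum((w * x)^2) / (128 * mean(w^2)),
                 tolerance = 1e-9)
  }
})

test_that("white-noise periodogram average is flat at 1/fs", {
  set.seed(24)
  fs <- 256
  acc <- numeric(65)
  for (i in 1:1000)
    acc <- acc + modified_periodogram(rnorm(128), nfft = 128, f_s = fs)$power
  avg <- acc / 1000
  interior <- avg[2:64]                 # skip the undoubled edge bins
  expect_lt(abs(mean(interior) - 2 / fs), 0.05 * 2 / fs)
  expect_lt(max(abs(interior - 2 / fs)), 0.2 * 2 / fs)
})

test_that("welch defaults average 13 padded periodograms on the N-line grid", {
  x <- semg_add_noise(semg_clean(250, seed = 31), 10, seed = 32)
  p <- welch_psd(x)
  expect_equal(p$meta$S, 13)
  expect_equal(p$meta$M, 64)
  expect_length(p$frequency, 129)                       # N/2 + 1 lines
  expect_equal(p$frequency[2] - p$frequency[1], 1024 / 256)
  expect_true(all(p$power >= 0))
})

test_that("single full-length rectangular segment equals the periodogram", {
  set.seed(33)
  x <- rnorm(256)
  w <- welch_psd(x, f_s = 1024, window_fraction = 1, step_fraction = 1,
                 taper = 0, demean = FALSE)
  pg <- modified_periodogram(x, rep(1, 256), nfft = 256, f_s = 1024)
  expect_equal(w$power, pg$power, tolerance = 1e-12)
})

test_that("segment averaging reduces the variance of the estimate", {
  set.seed(34)
  line <- 40                            # a fixed interior frequency line
  welch_vals <- numeric(500)
  pgram_vals <- numeric(500)
  for (i in 1:500) {
    x <- rnorm(256)
    welch_vals[i] <- welch_psd(x, f_s = 1024, demean = FALSE)$power[line]
    pgram_vals[i] <- modified_periodogram(x, nfft = 256, f_s = 1024)$power[line]
  }
  expect_lt(var(welch_vals), var(pgram_vals))
})

test_that("welch and burg estimates share the same frequency grid", {
  x <- semg_add_noise(semg_clean(500, seed = 41), 10, seed = 42)
  pw <- welch_psd(x)
  pb <- burg_psd(burg(x, 7))
  expect_equal(pw$frequency, pb$frequency)
})
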