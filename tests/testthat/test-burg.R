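# Burg lattice: brute-force oracle equivalence, parameter recovery,
# stability, spectral scaling, and the fitted-model methods.

test_that("stage-1 reflection coefficient matches a 1-D numeric minimizer", {
  for (seed in 1:5) {
    set.seed(seed)
    x <- rnorm(48)
    fit <- burg(x, 1, demean = FALSE)
    k_brute <- brute_reflection(x[-1], x[-length(x)])
    expect_equal(fit$reflection[1], k_brute, tolerance = 1e-6)
  }
})

test_that("full recursion agrees with the brute-force stage minimizer (N <= 64, p <= 4)", {
  for (seed in 1:4) {
    for (p in 1:4) {
      set.seed(100 + seed)
      x <- ar1_series(64, phi = 0.6, seed = 100 + seed)
      fit <- burg(x, p, demean = FALSE)
      oracle <- brute_burg(x, p)
      expect_equal(fit$reflection, oracle$k, tolerance = 1e-6)
      expect_equal(fit$a, oracle$a, tolerance = 1e-6)
    }
  }
})

test_that("coefficients agree with the reference Burg implementation", {
  x <- ar1_series(512, phi = 0.8, seed = 9)
  for (p in c(1, 3, 7)) {
    fit <- burg(x, p)
    ref <- stats::ar(x, aic = FALSE, order.max = p, method = "burg")
    expect_equal(unname(coef(fit)), unname(ref$ar), tolerance = 1e-8)
  }
})

test_that("known AR(1) process is recovered from long data", {
  x <- ar1_series(4096, phi = 0.9, seed = 13)
  fit <- burg(x, 1)
  expect_lt(abs(coef(fit)[["ar1"]] - 0.9), 0.02)
  expect_lt(abs(fit$sigma2 - 1), 0.1)
})

test_that("reflection coefficients are stable and error power non-increasing", {
  for (seed in 1:8) {
    set.seed(200 + seed)
    x <- cumsum(rnorm(128)) + rnorm(128)   # strongly coloured input
    fit <- burg(x, 10)
    expect_true(all(abs(fit$reflection) < 1))
    expect_true(all(diff(fit$var_stage) <= 1e-12))
    expect_gt(fit$sigma2, 0)
  }
})

test_that("degenerate and invalid inputs error", {
  expect_error(burg(rep(2, 100), 3), "constant")
  expect_error(burg(rnorm(10), 10), "smaller")
  expect_error(burg(rnorm(10), 0), "at least 1")
})

test_that("AR spectrum of white noise is approximately flat", {
  set.seed(15)
  x <- rnorm(4096)
  p <- burg_psd(burg(x, 3), f_s = 1024, nfft = 4096)
  interior <- p$power[2:(length(p$power) - 1)]
  expect_lt(max(interior) / min(interior), 3)
})

test_that("integrated AR spectrum conserves the signal power", {
  set.seed(16)
  x <- rnorm(4096)
  p <- burg_psd(burg(x, 3), f_s = 1024, nfft = 4096)
  df <- p$frequency[2] - p$frequency[1]
  expect_equal(sum(p$power) * df, var(x), tolerance = 0.05)
})

test_that("all study orders fit a short 256-sample signal", {
  y <- semg_add_noise(semg_clean(250, seed = 17), 10, seed = 18)
  for (p in c(3, 4, 7, 10, 15, 30)) {
    fit <- burg(y, p)
    expect_equal(fit$order, p)
    sp <- burg_psd(fit)
    expect_true(all(is.finite(sp$power)))
    expect_true(all(sp$power >= 0))
  }
})

test_that("fitted-model methods are mutually consistent", {
  x <- ar1_series(2048, phi = 0.9, seed = 19)
  fit <- burg(x, 2)
  # residual variance matches the lattice error power
  expect_equal(var(residuals(fit)), fit$sigma2, tolerance = 0.05)
  # fitted + residuals reconstructs the series tail
  expect_equal(fitted(fit) + residuals(fit), x[-(1:2)] - fit$x_mean + fit$x_mean,
               tolerance = 1e-10)
  # one-step forecast is the AR linear combination of the last samples
  phi <- coef(fit)
  expect_equal(predict(fit, n.ahead = 1),
               sum(phi * rev(tail(fit$x, 2))) + fit$x_mean, tolerance = 1e-10)
  # simulate is seeded and reproduces the fitted second-order structure
  s1 <- simulate(fit, nsim = 4096, seed = 77)
  s2 <- simulate(fit, nsim = 4096, seed = 77)
  expect_identical(s1, s2)
  refit <- burg(s1, 2)
  expect_equal(unname(coef(refit)), unname(phi), tolerance = 0.1)
})
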