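# Independent oracles used across the suite.  They deliberately avoid the
# package's FFT/recursion code paths: direct DFT sums, 1-D numeric
# minimization, closed-form substitutions.

# one-sided modified periodogram by direct DFT summation (density scaling)
naive_periodogram <- function(x, w, nfft, fs) {
  m <- length(x)
  half <- nfft / 2 + 1
  p <- vapply(0:(nfft / 2), function(k) {
    X <- sum(w * x * exp(-2i * pi * (0:(m - 1)) * k / nfft))
    Mod(X)^2
  }, numeric(1)) / (m * mean(w^2) * fs)
  p[2:(half - 1)] <- 2 * p[2:(half - 1)]
  p
}

# reflection coefficient by numeric minimization of the summed forward +
# backward squared prediction error (no closed form used)
brute_reflection <- function(fm, bm) {
  stats::optimize(function(k) sum((fm + k * bm)^2) + sum((bm + k * fm)^2),
                  interval = c(-1, 1), tol = 1e-12)$minimum
}

# stage-wise Burg fit driven entirely by the brute-force minimizer
brute_burg <- function(x, p) {
  f <- x; b <- x; a <- 1; ks <- numeric(p)
  for (m in seq_len(p)) {
    fm <- f[-1]; bm <- b[-length(b)]
    k <- brute_reflection(fm, bm)
    f <- fm + k * bm
    b <- bm + k * fm
    a <- c(a, 0) + k * rev(c(a, 0))
    ks[m] <- k
  }
  list(k = ks, a = a)
}

# seeded AR(1) draw used by several tests
ar1_series <- function(n, phi = 0.9, seed = 1) {
  set.seed(seed)
  as.numeric(stats::filter(rnorm(n), phi, method = "recursive"))
}

# small helper: flat white-spectrum semg_psd
flat_psd <- function(level = 1, f_s = 1024, n_lines = 513) {
  semg_psd(seq(0, f_s / 2, length.out = n_lines), rep(level, n_lines), f_s)
}
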