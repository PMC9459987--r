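#' Tukey (tapered cosine) window
#'
#' Rectangular centre with raised-cosine tapers covering a fraction
#' \code{taper} of the window (taper 0 is rectangular, 1 is a Hann window).
#'
#' @param n window length in samples.
#' @param taper taper fraction in \code{[0, 1]}.
#' @return Numeric vector of \code{n} window coefficients in \code{[0, 1]}.
#' @export
tukey_window <- function(n, taper = 0.5) {
  if (n < 1) stop("'n' must be positive")
  if (taper < 0 || taper > 1) stop("'taper' must be in [0, 1]")
  if (n == 1) return(1)
  t <- seq(0, 1, length.out = n)
  w <- rep(1, n)
  if (taper > 0) {
    lo <- t < taper / 2
    hi <- t > 1 - taper / 2
    w[lo] <- 0.5 * (1 + cos(pi * (2 * t[lo] / taper - 1)))
    w[hi] <- 0.5 * (1 + cos(pi * (2 * t[hi] / taper - 2 / taper + 1)))
  }
  w
}

#' Split a signal into overlapping segments
#'
#' Segment length is \code{M = round(window_fraction * N)} and the hop is
#' \code{round(step_fraction * M)}; segments start at 0, hop, 2 hop, ...
#' while fully inside the signal, giving
#' \code{S = floor((N - M)/hop) + 1} segments.  With the defaults
#' (window 25\% of the signal, hop 25\% of the window, i.e. 75\% overlap)
#' every signal yields 13 segments regardless of its length.
#'
#' @param x numeric signal or \code{semg_realization}.
#' @param window_fraction segment length as a fraction of the signal.
#' @param step_fraction hop as a fraction of the segment length.
#' @return List of numeric segments with attributes \code{M} (segment
#'   length), \code{hop}, and \code{starts} (0-based offsets).
#' @export
segment_signal <- function(x, window_fraction = 0.25, step_fraction = 0.25) {
  if (inherits(x, "semg_realization")) x <- x$samples
  n <- length(x)
  m <- as.integer(round(window_fraction * n))
  if (m < 8L) stop("segment length below 8 samples; increase 'window_fraction' or the signal length")
  if (m > n) stop("segment longer than the signal")
  hop <- as.integer(round(step_fraction * m))
  if (hop < 1L) stop("hop of zero samples; increase 'step_fraction'")
  starts <- seq.int(0L, n - m, by = hop)
  segs <- lapply(starts, function(s) x[(s + 1L):(s + m)])
  attr(segs, "M") <- m
  attr(segs, "hop") <- hop
  attr(segs, "starts") <- starts
  segs
}

#' Modified periodogram of one windowed segment
#'
#' One-sided density estimate
#' \deqn{I(f) = |\mathrm{DFT}(w x)|^2 / (M U f_s),\quad U = \frac1M\sum w_m^2,}
#' where \code{U} compensates the power lost to the window.  The segment
#' is zero-padded to \code{nfft} points and interior lines are doubled.
#'
#' @param segment numeric segment of length M.
#' @param window window coefficients, length M (see \code{\link{tukey_window}}).
#' @param nfft transform length (even, at least M); zero-padding allowed.
#' @param f_s sampling rate in Hz.
#' @return A \code{\link{semg_psd}} with \code{nfft/2 + 1} lines spaced
#'   \code{f_s/nfft} Hz.
#' @export
modified_periodogram <- function(segment, window = rep(1, length(segment)),
                                 nfft = length(segment), f_s = 1024) {
  m <- length(segment)
  if (length(window) != m) stop("'window' must match the segment length")
  if (all(window == 0)) stop("all-zero window")
  nfft <- as.integer(nfft)
  if (nfft < m) stop("'nfft' must be at least the segment length")
  if (nfft %% 2L != 0L) stop("'nfft' must be even")
  u <- mean(window^2)
  X <- fft(c(segment * window, rep(0, nfft - m)))
  half <- nfft / 2L + 1L
  p <- abs(X[seq_len(half)])^2 / (m * u * f_s)
  p[2:(half - 1L)] <- 2 * p[2:(half - 1L)]
  semg_psd((0:(half - 1L)) * f_s / nfft, p, f_s = f_s, method = "periodogram",
           meta = list(M = m, U = u, nfft = nfft))
}

#' Welch PSD estimate (averaged modified periodograms)
#'
#' Averages the modified periodograms of overlapping Tukey-windowed
#' segments.  Defaults follow the study protocol for fatigued sEMG:
#' segment length 25\% of the signal, hop 25\% of the segment (13 segments
#' for any signal length), Tukey taper 0.5, every segment zero-padded to
#' the full signal length so the frequency grid has \code{N/2 + 1} lines
#' spaced \code{f_s/N} Hz, and per-segment mean removal.
#'
#' @param x numeric signal or \code{\link{semg_clean}} realization.
#' @param f_s sampling rate in Hz (taken from the realization if given).
#' @param window_fraction,step_fraction see \code{\link{segment_signal}}.
#' @param taper Tukey taper fraction.
#' @param nfft transform length; defaults to the signal length.
#' @param demean remove each segment's mean before windowing.
#' @return A \code{\link{semg_psd}} with method tag \code{"welch"}; the
#'   number of segments is in \code{meta$S}.
#' @examples
#' x <- semg_add_noise(semg_clean(1000, seed = 1), 10, seed = 2)
#' welch_psd(x)
#' @export
welch_psd <- function(x, f_s = 1024, window_fraction = 0.25,
                      step_fraction = 0.25, taper = 0.5, nfft = NULL,
                      demean = TRUE) {
  if (inherits(x, "semg_realization")) {
    f_s <- x$f_s
    x <- x$samples
  }
  n <- length(x)
  if (is.null(nfft)) nfft <- n
  segs <- segment_signal(x, window_fraction, step_fraction)
  m <- attr(segs, "M")
  w <- tukey_window(m, taper)
  acc <- NULL
  for (seg in segs) {
    if (demean) seg <- seg - mean(seg)
    pg <- modified_periodogram(seg, w, nfft = nfft, f_s = f_s)
    acc <- if (is.null(acc)) pg$power else acc + pg$power
  }
  s <- length(segs)
  semg_psd(pg$frequency, acc / s, f_s = f_s, method = "welch",
           meta = list(S = s, M = m, hop = attr(segs, "hop"), taper = taper,
                       U = mean(w^2), nfft = nfft, demean = demean))
}
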