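#' Minimum-phase shaping filter for a target power spectrum
#'
#' Designs the FIR filter used to colour white Gaussian noise so that the
#' output PSD matches a target spectrum.  The amplitude response is the
#' square root of the target PSD sampled on a dense grid; the phase is the
#' minimum-phase reconstruction obtained from the Hilbert transform of the
#' log-magnitude (implemented through the real cepstrum), so the impulse
#' response is real and causal with its energy packed into the leading
#' taps.  The magnitude is floored at \code{mag_floor} times its maximum
#' before the logarithm, which regularizes the exact zero of the target
#' spectrum at DC.
#'
#' @param spec target spectrum: a \code{\link{semg_psd}} (typically from
#'   \code{\link{ideal_spectrum}}) or a list with \code{k}, \code{f_l},
#'   \code{f_h}, \code{f_s} parameters of \code{\link{ideal_psd}}.
#' @param n_taps length of the returned impulse response; at least 64.
#' @param nfft design-grid length (even); defaults to the larger of 4096
#'   and four times \code{n_taps}.
#' @param mag_floor relative magnitude floor applied before the log.
#' @return An object of class \code{shaping_filter}: list with the impulse
#'   response \code{h}, \code{f_s}, and design metadata.
#' @examples
#' filt <- shaping_filter(ideal_spectrum(), n_taps = 256)
#' plot(filter_response(filt))
#' @export
shaping_filter <- function(spec = ideal_spectrum(), n_taps = 512,
                           nfft = NULL, mag_floor = 1e-12) {
  if (n_taps < 64) stop("'n_taps' must be at least 64")
  if (is.null(nfft)) nfft <- max(4096L, 4L * as.integer(2^ceiling(log2(n_taps))))
  nfft <- as.integer(nfft)
  if (nfft %% 2L != 0L) stop("'nfft' must be even")
  if (nfft < 2L * n_taps) stop("'nfft' must be at least twice 'n_taps'")

  if (inherits(spec, "semg_psd")) {
    f_s <- spec$f_s
    target <- function(f) {
      # clamp to the tabulated grid; interpolate linearly
      approx(spec$frequency, spec$power, xout = pmin(f, max(spec$frequency)),
             rule = 2)$y
    }
    meta <- spec$meta
  } else {
    f_s <- spec$f_s %||% 1024
    target <- function(f) ideal_psd(f, k = spec$k %||% 1,
                                    f_l = spec$f_l %||% 20,
                                    f_h = spec$f_h %||% 40)
    meta <- spec
  }

  f <- (0:(nfft - 1L)) * f_s / nfft
  f_folded <- pmin(f, f_s - f)              # conjugate-symmetric magnitude
  A <- sqrt(pmax(target(f_folded), 0))
  A <- pmax(A, mag_floor * max(A))

  # minimum-phase reconstruction via the real cepstrum: fold the cepstrum
  # of log|A| onto causal quefrencies, exponentiate back
  cep <- Re(fft(log(A), inverse = TRUE)) / nfft
  fold <- c(1, rep(2, nfft / 2L - 1L), 1, rep(0, nfft / 2L - 1L))
  H <- exp(fft(cep * fold))
  h_full <- Re(fft(H, inverse = TRUE)) / nfft

  structure(
    list(h = h_full[seq_len(n_taps)], n_taps = as.integer(n_taps),
         f_s = f_s, nfft = nfft, mag_floor = mag_floor, target = meta),
    class = "shaping_filter")
}

#' @export
print.shaping_filter <- function(x, ...) {
  cat(sprintf("Minimum-phase shaping filter: %d taps at f_s = %g Hz (design grid %d)\n",
              x$n_taps, x$f_s, x$nfft))
  e <- cumsum(x$h^2) / sum(x$h^2)
  cat(sprintf("  90%% of impulse-response energy within the first %d taps\n",
              which(e >= 0.9)[1L]))
  invisible(x)
}

#' Magnitude-squared frequency response of a shaping filter
#'
#' @param filt a \code{\link{shaping_filter}}.
#' @param nfft transform length for the evaluation grid (even; default 4096).
#' @return A \code{\link{semg_psd}} holding \eqn{|H(f)|^2} on
#'   \code{[0, f_s/2]}.
#' @export
filter_response <- function(filt, nfft = 4096L) {
  stopifnot(inherits(filt, "shaping_filter"))
  nfft <- as.integer(nfft)
  if (nfft < filt$n_taps) stop("'nfft' must be at least the filter length")
  if (nfft %% 2L != 0L) stop("'nfft' must be even")
  H <- fft(c(filt$h, rep(0, nfft - filt$n_taps)))
  f <- (0:(nfft / 2L)) * filt$f_s / nfft
  semg_psd(f, abs(H[seq_len(nfft / 2L + 1L)])^2, f_s = filt$f_s,
           method = "filter_response", meta = list(n_taps = filt$n_taps))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
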