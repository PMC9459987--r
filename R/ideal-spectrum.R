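#' Band-pass spectral model of severely fatigued sEMG
#'
#' Evaluates the Stulen--De Luca band-pass power spectrum
#' \deqn{P(f) = \frac{k^2 f_h^4 f^2}{(f^2+f_l^2)(f^2+f_h^2)^2}}
#' that serves as the ideal (noise-free, infinite-data) PSD of the
#' synthetic signals.  With the default cut-offs \code{f_l = 20} Hz and
#' \code{f_h = 40} Hz the spectrum is compressed into the low-frequency
#' band, emulating severe myoelectric fatigue.  The shape vanishes at DC
#' (the \eqn{f^2} numerator), peaks between \code{f_l} and \code{f_h}, and
#' decays as \eqn{f^{-4}} in the tail.
#'
#' @param f frequency (Hz); vectorized, must be nonnegative.
#' @param k dimensionless scale factor (enters as \code{k^2}).
#' @param f_l low cut-off frequency (Hz), positive.
#' @param f_h high cut-off frequency (Hz), positive.
#' @return PSD ordinates (arbitrary power per Hz), same length as \code{f}.
#' @examples
#' ideal_psd(40)          # 0.2 at the high cut-off with the defaults
#' @export
ideal_psd <- function(f, k = 1, f_l = 20, f_h = 40) {
  if (any(f < 0)) stop("frequencies must be nonnegative")
  if (f_l <= 0 || f_h <= 0) stop("cut-off frequencies must be positive")
  k^2 * f_h^4 * f^2 / ((f^2 + f_l^2) * (f^2 + f_h^2)^2)
}

#' Ideal PSD evaluated on a dense frequency grid
#'
#' Convenience constructor returning the model of \code{\link{ideal_psd}}
#' as a \code{\link{semg_psd}} over \code{[0, f_s/2]}.
#'
#' @inheritParams ideal_psd
#' @param f_s sampling rate (Hz).
#' @param grid_step grid spacing (Hz).
#' @return A \code{\link{semg_psd}} with method tag \code{"ideal"}.
#' @export
ideal_spectrum <- function(k = 1, f_l = 20, f_h = 40, f_s = 1024,
                           grid_step = 0.01) {
  if (f_s <= 0 || grid_step <= 0) stop("'f_s' and 'grid_step' must be positive")
  f <- seq(0, f_s / 2, by = grid_step)
  semg_psd(f, ideal_psd(f, k, f_l, f_h), f_s = f_s, method = "ideal",
           meta = list(k = k, f_l = f_l, f_h = f_h, grid_step = grid_step))
}
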