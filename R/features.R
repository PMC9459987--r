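#' Mean frequency of a power spectrum
#'
#' Power-weighted mean of the grid frequencies,
#' \eqn{\mathrm{MNF} = \sum_l P_l f_l / \sum_l P_l}.
#'
#' @param x a \code{\link{semg_psd}}, or a numeric frequency vector (Hz)
#'   with the ordinates supplied in \code{power}.
#' @param power PSD ordinates (only for the default method).
#' @param ... passed between methods.
#' @return Mean frequency in Hz.
#' @export
mnf <- function(x, ...) UseMethod("mnf")

#' @rdname mnf
#' @export
mnf.semg_psd <- function(x, ...) mnf.default(x$frequency, x$power)

#' @rdname mnf
#' @export
mnf.default <- function(x, power, ...) {
  tot <- sum(power)
  if (!is.finite(tot) || tot <= 0) stop("zero or invalid total power")
  sum(power * x) / tot
}

#' Median frequency of a power spectrum
#'
#' Frequency at which the cumulative power reaches half of the total.  By
#' default the crossing is located by linear interpolation of the
#' cumulative-power curve, with each line's power treated as centred on
#' its frequency (so a single nonzero line returns exactly that
#' frequency and a symmetric spectrum is split without half-bin bias);
#' this removes the grid-resolution bias of short signals.
#' \code{interpolate = FALSE} snaps to the first line at or past the
#' half-power point (strict index semantics).
#'
#' @inheritParams mnf
#' @param interpolate interpolate the half-power crossing (default TRUE).
#' @return Median frequency in Hz.
#' @export
mdf <- function(x, ...) UseMethod("mdf")

#' @rdname mdf
#' @export
mdf.semg_psd <- function(x, interpolate = TRUE, ...)
  mdf.default(x$frequency, x$power, interpolate = interpolate)

#' @rdname mdf
#' @export
mdf.default <- function(x, power, interpolate = TRUE, ...) {
  tot <- sum(power)
  if (!is.finite(tot) || tot <= 0) stop("zero or invalid total power")
  cum <- cumsum(power)
  half <- tot / 2
  if (!interpolate) return(x[which(cum >= half)[1L]])
  # centre each line's power on its own frequency and invert the
  # piecewise-linear cumulative curve
  ccum <- cum - power / 2
  i <- which(ccum >= half)[1L]
  if (is.na(i)) return(x[length(x)])
  if (i == 1L) return(x[1L])
  x[i - 1L] + (half - ccum[i - 1L]) / (ccum[i] - ccum[i - 1L]) * (x[i] - x[i - 1L])
}

#' Spectral features of a PSD
#'
#' @param psd a \code{\link{semg_psd}}.
#' @param source optional provenance tag overriding the PSD's method tag.
#' @return A one-row data frame with class \code{spectral_features}:
#'   \code{mnf} (Hz), \code{mdf} (Hz), \code{total_power}, \code{source}.
#' @export
spectral_features <- function(psd, source = NULL) {
  stopifnot(inherits(psd, "semg_psd"))
  out <- data.frame(mnf = mnf(psd), mdf = mdf(psd),
                    total_power = total_power(psd),
                    source = source %||% psd$method,
                    stringsAsFactors = FALSE)
  class(out) <- c("spectral_features", "data.frame")
  out
}

#' Analytic reference MNF/MDF of the fatigue spectrum
#'
#' Evaluates the ideal band-pass spectrum (\code{\link{ideal_psd}}) on a
#' dense grid over \code{[0, f_s/2]} and extracts its mean and median
#' frequency.  These are the ground-truth values \eqn{y_d} against which
#' every estimator error in the Monte-Carlo study is measured.  With the
#' defaults (k = 1, cut-offs 20/40 Hz, f_s = 1024 Hz) the reference is
#' MNF 40.76 Hz, MDF 31.89 Hz, converged to well under 0.01 Hz at the
#' default grid step.
#'
#' @inheritParams ideal_spectrum
#' @return A \code{\link{spectral_features}} row with source \code{"ideal"}.
#' @examples
#' ideal_reference()
#' @export
ideal_reference <- function(f_l = 20, f_h = 40, f_s = 1024, grid_step = 0.01,
                            k = 1) {
  if (grid_step > 0.01)
    warning("grid_step above 0.01 Hz; reference values may not be converged")
  spectral_features(ideal_spectrum(k, f_l, f_h, f_s, grid_step), source = "ideal")
}
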