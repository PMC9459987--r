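#' One-sided power spectral density container
#'
#' Light S3 container shared by every PSD producer in the package
#' (\code{\link{ideal_spectrum}}, \code{\link{welch_psd}},
#' \code{\link{burg_psd}}).  Frequencies run from 0 to the Nyquist
#' frequency; ordinates are a one-sided density (power per Hz) with the
#' interior lines carrying the doubled two-sided power.
#'
#' @param frequency strictly increasing frequency grid in Hz, starting at 0.
#' @param power nonnegative PSD ordinates, same length as \code{frequency}.
#' @param f_s sampling rate in Hz.
#' @param method character tag identifying the producer
#'   (\code{"ideal"}, \code{"welch"}, \code{"burg"}, ...).
#' @param meta list of producer-specific parameters.
#' @return An object of class \code{semg_psd}: a list with elements
#'   \code{frequency}, \code{power}, \code{f_s}, \code{method}, \code{meta}.
#' @seealso \code{\link{mnf}}, \code{\link{mdf}}, \code{\link{write_psd}}
#' @export
semg_psd <- function(frequency, power, f_s, method = "custom", meta = list()) {
  frequency <- as.numeric(frequency)
  power <- as.numeric(power)
  if (length(frequency) != length(power))
    stop("'frequency' and 'power' must have equal length")
  if (length(frequency) < 2L || any(diff(frequency) <= 0))
    stop("'frequency' must be strictly increasing with at least 2 lines")
  if (frequency[1L] < 0)
    stop("'frequency' must be nonnegative")
  if (any(!is.finite(power)) || any(power < -1e-12 * max(abs(power))))
    stop("'power' must be finite and nonnegative")
  power[power < 0] <- 0
  structure(
    list(frequency = frequency, power = power, f_s = as.numeric(f_s),
         method = as.character(method), meta = meta),
    class = "semg_psd")
}

#' @export
print.semg_psd <- function(x, ...) {
  cat(sprintf("One-sided PSD (%s): %d lines, %.3g-%.6g Hz, df = %.4g Hz\n",
              x$method, length(x$frequency), x$frequency[1L],
              x$frequency[length(x$frequency)], x$frequency[2L] - x$frequency[1L]))
  cat(sprintf("  total power %.4g, MNF %.2f Hz, MDF %.2f Hz\n",
              total_power(x), mnf(x), mdf(x)))
  invisible(x)
}

#' @export
as.data.frame.semg_psd <- function(x, ...) {
  data.frame(frequency_hz = x$frequency, psd = x$power)
}

#' @export
plot.semg_psd <- function(x, log = "", xlab = "Frequency (Hz)",
                          ylab = "PSD (power/Hz)", type = "l",
                          main = sprintf("PSD (%s)", x$method), ...) {
  plot(x$frequency, x$power, type = type, log = log,
       xlab = xlab, ylab = ylab, main = main, ...)
  invisible(x)
}

#' Export / import a PSD as a two-column CSV
#'
#' Columns are \code{frequency_hz} and \code{psd}.  Metadata (sampling
#' rate, method) is stored in \code{#}-prefixed header lines so the file
#' round-trips through \code{read_psd}.
#'
#' @param psd a \code{\link{semg_psd}} object.
#' @param path file path.
#' @return \code{write_psd} returns \code{path} invisibly; \code{read_psd}
#'   returns a \code{semg_psd}.
#' @export
write_psd <- function(psd, path) {
  stopifnot(inherits(psd, "semg_psd"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# f_s=%.10g", psd$f_s), con)
  writeLines(sprintf("# method=%s", psd$method), con)
  writeLines("frequency_hz,psd", con)
  writeLines(sprintf("%.12g,%.12g", psd$frequency, psd$power), con)
  invisible(path)
}

#' @rdname write_psd
#' @export
read_psd <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key, default) {
    m <- sub(paste0("^#\\s*", key, "="), "", grep(paste0("^#\\s*", key, "="), hdr, value = TRUE))
    if (length(m)) m[1L] else default
  }
  dat <- read.csv(text = lines[!grepl("^#", lines)])
  semg_psd(dat$frequency_hz, dat$psd, f_s = as.numeric(get("f_s", 2 * max(dat$frequency_hz))),
           method = get("method", "custom"))
}

total_power <- function(psd) {
  df <- psd$frequency[2L] - psd$frequency[1L]
  sum(psd$power) * df
}
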