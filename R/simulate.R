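#' Synthesize one clean fatigued-sEMG realization
#'
#' Draws a seeded zero-mean unit-variance white Gaussian input, colours it
#' with the minimum-phase shaping filter, and returns exactly
#' \code{N = round(duration_ms * f_s / 1000)} steady-state output samples.
#' The filter's start-up transient is avoided by synthesizing
#' \code{N + n_taps} input samples and keeping the last \code{N} fully
#' immersed outputs of the linear convolution.
#'
#' @param duration_ms signal duration in milliseconds (positive).
#' @param filt a \code{\link{shaping_filter}}; by default the filter for the
#'   severe-fatigue spectrum (\code{\link{ideal_spectrum}}) with
#'   \code{min(N, 512)} taps.
#' @param seed integer seed for the white-noise input stream (reproducible);
#'   \code{NULL} leaves the RNG state alone.
#' @param realization optional realization index stored as metadata.
#' @return An object of class \code{semg_realization}: list with
#'   \code{samples}, \code{n}, \code{duration_ms}, \code{f_s},
#'   \code{snr_db} (\code{Inf} for a clean signal), \code{seed_signal},
#'   \code{seed_noise}, \code{realization}.
#' @examples
#' x <- semg_clean(250, seed = 1)
#' x$n   # 256 samples at 1024 Hz
#' @export
semg_clean <- function(duration_ms, filt = NULL, seed = NULL,
                       realization = NA_integer_) {
  if (duration_ms <= 0) stop("'duration_ms' must be positive")
  f_s <- if (is.null(filt)) 1024 else filt$f_s
  n <- as.integer(round(duration_ms * f_s / 1000))
  if (n < 1L) stop("duration too short: fewer than one sample at f_s")
  if (is.null(filt)) filt <- cached_default_filter(min(n, 512L))
  L <- filt$n_taps
  if (!is.null(seed)) set.seed(as.integer(seed))
  g <- rnorm(n + L)
  y_full <- convolve(g, rev(filt$h), type = "open")   # length n + 2L - 1
  samples <- y_full[L + seq_len(n)]                   # steady state only
  if (var(samples) <= 0) stop("degenerate clean signal (zero variance)")
  structure(
    list(samples = samples, n = n, duration_ms = duration_ms, f_s = f_s,
         snr_db = Inf, seed_signal = if (is.null(seed)) NA_integer_ else as.integer(seed),
         seed_noise = NA_integer_, realization = realization),
    class = "semg_realization")
}

# the default severe-fatigue filter depends only on its tap count; cache it
.filter_cache <- new.env(parent = emptyenv())
cached_default_filter <- function(n_taps) {
  key <- as.character(n_taps)
  if (is.null(.filter_cache[[key]]))
    .filter_cache[[key]] <- shaping_filter(ideal_spectrum(), n_taps = max(64L, n_taps))
  .filter_cache[[key]]
}

#' Add white Gaussian measurement noise at a prescribed SNR
#'
#' The noise draw is rescaled against the empirical power of the clean
#' signal so that \code{10*log10(mean(signal^2)/mean(noise^2))} equals
#' \code{snr_db} exactly for every finite realization.  The noise stream
#' is independent of the signal stream (separate seed).
#'
#' @param x a clean \code{\link{semg_clean}} realization.
#' @param snr_db target signal-to-noise ratio in dB; \code{Inf} returns the
#'   input unchanged.
#' @param seed integer seed for the noise stream.
#' @return A \code{semg_realization} with \code{snr_db} set.
#' @export
semg_add_noise <- function(x, snr_db, seed = NULL) {
  stopifnot(inherits(x, "semg_realization"))
  if (!is.finite(snr_db)) return(x)
  p_sig <- mean(x$samples^2)
  if (p_sig <= 0) stop("zero-power input signal")
  if (!is.null(seed)) set.seed(as.integer(seed))
  q <- rnorm(x$n)
  # normalize the draw so the realized noise power hits the target exactly
  q <- q * sqrt(p_sig / 10^(snr_db / 10) / mean(q^2))
  x$samples <- x$samples + q
  x$snr_db <- snr_db
  x$seed_noise <- if (is.null(seed)) NA_integer_ else as.integer(seed)
  x
}

#' @export
print.semg_realization <- function(x, ...) {
  cat(sprintf("sEMG realization: %d samples (%g ms at %g Hz), SNR %s dB\n",
              x$n, x$duration_ms, x$f_s,
              if (is.finite(x$snr_db)) format(x$snr_db) else "Inf (clean)"))
  invisible(x)
}

#' @export
plot.semg_realization <- function(x, xlab = "Time (ms)", ylab = "Amplitude (a.u.)", ...) {
  t_ms <- (seq_len(x$n) - 1) / x$f_s * 1000
  plot(t_ms, x$samples, type = "l", xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Write / read a realization as single-column plain text
#'
#' The file holds one sample per line, preceded by \code{#} header lines
#' recording sampling rate, duration, SNR and the seeds, so a written
#' signal round-trips exactly (to the printed precision).
#'
#' @param x a \code{semg_realization}.
#' @param path file path.
#' @return \code{write_semg} returns \code{path} invisibly;
#'   \code{read_semg} returns a \code{semg_realization}.
#' @export
write_semg <- function(x, path) {
  stopifnot(inherits(x, "semg_realization"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# f_s=%.10g", x$f_s),
               sprintf("# duration_ms=%.10g", x$duration_ms),
               sprintf("# snr_db=%s", format(x$snr_db, digits = 10)),
               sprintf("# seed_signal=%s", x$seed_signal),
               sprintf("# seed_noise=%s", x$seed_noise),
               sprintf("# realization=%s", x$realization)), con)
  writeLines(sprintf("%.12g", x$samples), con)
  invisible(path)
}

#' @rdname write_semg
#' @export
read_semg <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key, default = NA) {
    m <- sub(paste0("^#\\s*", key, "="), "",
             grep(paste0("^#\\s*", key, "="), hdr, value = TRUE))
    if (length(m)) m[1L] else default
  }
  samples <- as.numeric(lines[!grepl("^#", lines)])
  f_s <- as.numeric(get("f_s", 1024))
  structure(
    list(samples = samples, n = length(samples),
         duration_ms = as.numeric(get("duration_ms", length(samples) / f_s * 1000)),
         f_s = f_s, snr_db = as.numeric(get("snr_db", Inf)),
         seed_signal = suppressWarnings(as.integer(get("seed_signal"))),
         seed_noise = suppressWarnings(as.integer(get("seed_noise"))),
         realization = suppressWarnings(as.integer(get("realization")))),
    class = "semg_realization")
}

#' Derive a reproducible sub-stream seed from a tuple of integers
#'
#' Deterministic multiplicative hash mapping any tuple (master seed, cell
#' indices, realization index, stream tag) to a seed in
#' \code{[1, 2^31 - 2]}.  The study uses it to give every realization two
#' independent, individually reproducible RNG streams (signal and noise),
#' so any cell of the grid can be regenerated in isolation.  Doubles carry
#' the arithmetic exactly (69069 * 2^31 < 2^53).
#'
#' @param ... integers to mix.
#' @return A single integer seed.
#' @examples
#' mix_seed(1, 2, 17, 1)  # signal stream of realization 17
#' @export
mix_seed <- function(...) {
  v <- c(...)
  h <- 104729
  for (x in v) h <- (h * 69069 + (as.numeric(x) %% 2147483647) + 1) %% 2147483647
  as.integer(h + 1)
}
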