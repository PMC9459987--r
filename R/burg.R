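#' Fit an autoregressive model by Burg's lattice method
#'
#' Classic Burg recursion: at each stage \code{m} the reflection
#' coefficient is chosen to minimize the summed forward and backward
#' squared prediction errors,
#' \deqn{k_m = \frac{-2\sum f_m(n) b_m(n-1)}{\sum f_m(n)^2 + \sum b_m(n-1)^2},}
#' the prediction coefficients are updated by the Levinson--Durbin step
#' \eqn{a_m = [a_{m-1}, 0] + k_m\,\mathrm{rev}([a_{m-1}, 0])}, and the
#' error power shrinks by \eqn{(1 - k_m^2)}.  All reflection coefficients
#' have magnitude below 1, so the fitted model is always stable.  The
#' model predicts \eqn{\hat x(n) = -\sum_{z=1}^p a_{pz} x(n-z)}.
#'
#' @param x numeric series or a \code{\link{semg_clean}} realization.
#' @param order AR model order \code{p} (at least 1, below \code{length(x)}).
#' @param demean subtract the sample mean before fitting (default TRUE).
#' @return An object of class \code{burg}: list with
#'   \describe{
#'     \item{order}{the order \code{p}.}
#'     \item{a}{monic prediction polynomial \code{c(1, a_p1, ..., a_pp)}.}
#'     \item{reflection}{per-stage reflection coefficients \code{k_1..k_p}.}
#'     \item{var_stage}{per-stage prediction-error powers (non-increasing).}
#'     \item{sigma2}{final prediction-error variance.}
#'     \item{x, n, x_mean, f_s}{the (centred) data and its metadata.}
#'   }
#' @seealso \code{\link{burg_psd}} for the spectral estimate;
#'   \code{coef}, \code{residuals}, \code{predict}, \code{simulate} and
#'   \code{plot} methods are provided.
#' @examples
#' set.seed(1)
#' x <- as.numeric(stats::filter(rnorm(2048), 0.9, method = "recursive"))
#' fit <- burg(x, order = 1)
#' coef(fit)        # close to 0.9
#' @export
burg <- function(x, order, demean = TRUE) {
  f_s <- 1024
  if (inherits(x, "semg_realization")) {
    f_s <- x$f_s
    x <- x$samples
  }
  x <- as.numeric(x)
  n <- length(x)
  order <- as.integer(order)
  if (order < 1L) stop("'order' must be at least 1")
  if (order >= n) stop("'order' must be smaller than the series length")
  x_mean <- if (demean) mean(x) else 0
  xc <- x - x_mean
  if (var(xc) == 0) stop("constant signal: Burg recursion is degenerate")
  rec <- burg_recursion(xc, order)
  structure(
    list(order = order, a = rec$a[[order]], reflection = rec$k,
         var_stage = rec$E, sigma2 = rec$E[order], e0 = rec$e0,
         x = xc, n = n, x_mean = x_mean, f_s = f_s,
         call = match.call()),
    class = "burg")
}

# Stage-wise Burg recursion up to order pmax; returns every intermediate
# model so one pass serves all study orders.
burg_recursion <- function(x, pmax) {
  n <- length(x)
  f <- x
  b <- x
  a <- 1
  e <- mean(x^2)
  k_vec <- numeric(pmax)
  e_vec <- numeric(pmax)
  a_list <- vector("list", pmax)
  for (m in seq_len(pmax)) {
    fm <- f[-1L]
    bm <- b[-length(b)]
    den <- sum(fm^2) + sum(bm^2)
    if (den == 0) stop("degenerate recursion: zero prediction error at stage ", m)
    k <- -2 * sum(fm * bm) / den
    f <- fm + k * bm
    b <- bm + k * fm
    a <- c(a, 0) + k * rev(c(a, 0))
    e <- e * (1 - k^2)
    k_vec[m] <- k
    e_vec[m] <- e
    a_list[[m]] <- a
  }
  list(k = k_vec, E = e_vec, a = a_list, e0 = mean(x^2))
}

#' @export
print.burg <- function(x, digits = 4, ...) {
  cat(sprintf("Burg AR(%d) fit on %d samples\n", x$order, x$n))
  cat("AR coefficients (x[n] = sum phi_z x[n-z] + e):\n")
  print(round(coef(x), digits))
  cat(sprintf("innovation variance sigma^2 = %.*g\n", digits, x$sigma2))
  invisible(x)
}

#' @export
coef.burg <- function(object, ...) {
  setNames(-object$a[-1L], paste0("ar", seq_len(object$order)))
}

#' @export
summary.burg <- function(object, ...) {
  structure(
    list(order = object$order, n = object$n, coef = coef(object),
         reflection = object$reflection, var_stage = object$var_stage,
         sigma2 = object$sigma2,
         variance_explained = 1 - object$sigma2 / object$e0),
    class = "summary.burg")
}

#' @export
print.summary.burg <- function(x, digits = 4, ...) {
  cat(sprintf("Burg AR(%d) fit on %d samples\n", x$order, x$n))
  cat("AR coefficients:\n"); print(round(x$coef, digits))
  cat("reflection coefficients (|k| < 1):\n")
  print(round(x$reflection, digits))
  cat("stage error powers (non-increasing):\n")
  print(signif(x$var_stage, digits))
  cat(sprintf("sigma^2 = %.*g (fraction of variance explained: %.3f)\n",
              digits, x$sigma2, x$variance_explained))
  invisible(x)
}

#' @export
residuals.burg <- function(object, ...) {
  # forward prediction errors over the fully initialised range
  p <- object$order
  x <- object$x
  n <- object$n
  idx <- (p + 1L):n
  pred <- numeric(length(idx))
  for (z in seq_len(p)) pred <- pred - object$a[z + 1L] * x[idx - z]
  x[idx] - pred
}

#' @export
fitted.burg <- function(object, ...) {
  p <- object$order
  object$x[(p + 1L):object$n] - residuals(object) + object$x_mean
}

#' @export
predict.burg <- function(object, n.ahead = 1, ...) {
  p <- object$order
  phi <- -object$a[-1L]
  hist <- tail(object$x, p)
  out <- numeric(n.ahead)
  for (i in seq_len(n.ahead)) {
    out[i] <- sum(phi * rev(hist))
    hist <- c(hist[-1L], out[i])
  }
  out + object$x_mean
}

#' @export
simulate.burg <- function(object, nsim = object$n, seed = NULL, burn = 500L, ...) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  phi <- -object$a[-1L]
  e <- rnorm(nsim + burn, sd = sqrt(object$sigma2))
  y <- as.numeric(stats::filter(e, phi, method = "recursive"))
  tail(y, nsim) + object$x_mean
}

#' @export
plot.burg <- function(x, nfft = max(1024L, x$n), log = "y", ...) {
  plot(burg_psd(x, f_s = x$f_s, nfft = nfft), log = log, ...)
}

#' Autoregressive PSD from a Burg fit
#'
#' Evaluates the AR spectral density
#' \deqn{P(f) = \frac{\sigma^2}{f_s\,|1 + \sum_{z=1}^p a_{pz} e^{-j 2\pi z f/f_s}|^2}}
#' on the one-sided grid \code{0..f_s/2} with spacing \code{f_s/nfft}
#' (interior lines doubled).  Using \code{nfft} equal to the signal length
#' puts Welch and Burg estimates on the same grid for per-line comparison.
#'
#' @param model a \code{\link{burg}} fit.
#' @param f_s sampling rate in Hz (defaults to the rate stored in the fit).
#' @param nfft transform length (even).
#' @return A \code{\link{semg_psd}} with method tag \code{"burg"}.
#' @export
burg_psd <- function(model, f_s = model$f_s, nfft = model$n) {
  stopifnot(inherits(model, "burg"))
  nfft <- as.integer(nfft)
  if (nfft %% 2L != 0L) stop("'nfft' must be even")
  if (nfft <= model$order) stop("'nfft' must exceed the model order")
  A <- fft(c(model$a, rep(0, nfft - length(model$a))))
  half <- nfft / 2L + 1L
  p <- model$sigma2 / (f_s * abs(A[seq_len(half)])^2)
  p[2:(half - 1L)] <- 2 * p[2:(half - 1L)]
  semg_psd((0:(half - 1L)) * f_s / nfft, p, f_s = f_s, method = "burg",
           meta = list(order = model$order, sigma2 = model$sigma2, nfft = nfft))
}
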