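#' Configuration of the factorial Monte-Carlo study
#'
#' Defaults reproduce the full study protocol: eight durations from 250 to
#' 2000 ms in 250 ms steps, SNR levels 5/10/15/20 dB, seven estimation
#' methods (Welch plus Burg orders 3, 4, 7, 10, 15 and 30), and 1000
#' realizations per condition at 1024 Hz with the severe-fatigue spectrum
#' (cut-offs 20/40 Hz).
#'
#' @param durations_ms signal durations in ms.
#' @param snr_db signal-to-noise ratios in dB.
#' @param methods character vector; \code{"welch"} and/or \code{"burg<p>"}.
#' @param realizations Monte-Carlo realizations per condition (>= 2).
#' @param master_seed master seed; every realization's two RNG streams are
#'   derived deterministically from it, so any cell can be regenerated in
#'   isolation.
#' @param k,f_l,f_h,f_s ideal-spectrum parameters (see \code{\link{ideal_psd}}).
#' @param taper Tukey taper fraction for the Welch estimator.
#' @param grid_step grid step (Hz) for the analytic reference values.
#' @return A validated list of class \code{study_config}.
#' @export
study_config <- function(durations_ms = seq(250, 2000, by = 250),
                         snr_db = c(5, 10, 15, 20),
                         methods = c("welch", paste0("burg", c(3, 4, 7, 10, 15, 30))),
                         realizations = 1000,
                         master_seed = 1,
                         k = 1, f_l = 20, f_h = 40, f_s = 1024,
                         taper = 0.5, grid_step = 0.01) {
  if (length(methods) < 1L) stop("at least one method required")
  bad <- !grepl("^(welch|burg[0-9]+)$", methods)
  if (any(bad)) stop("unknown method(s): ", paste(methods[bad], collapse = ", "))
  if (any(durations_ms <= 0)) stop("durations must be positive")
  if (realizations < 2) stop("at least 2 realizations required")
  cfg <- list(durations_ms = sort(unique(durations_ms)),
              snr_db = sort(unique(snr_db)),
              methods = unique(methods),
              realizations = as.integer(realizations),
              master_seed = as.integer(master_seed),
              k = k, f_l = f_l, f_h = f_h, f_s = f_s,
              taper = taper, grid_step = grid_step)
  class(cfg) <- "study_config"
  cfg
}

#' @export
print.study_config <- function(x, ...) {
  cat("Monte-Carlo study configuration\n")
  cat("  durations (ms):", paste(x$durations_ms, collapse = ", "), "\n")
  cat("  SNR (dB):      ", paste(x$snr_db, collapse = ", "), "\n")
  cat("  methods:       ", paste(x$methods, collapse = ", "), "\n")
  cat(sprintf("  realizations:   %d per condition, master seed %d\n",
              x$realizations, x$master_seed))
  cat(sprintf("  spectrum: k=%g, f_l=%g Hz, f_h=%g Hz, f_s=%g Hz\n",
              x$k, x$f_l, x$f_h, x$f_s))
  invisible(x)
}

burg_orders <- function(methods) {
  as.integer(sub("^burg", "", grep("^burg", methods, value = TRUE)))
}

# MNF/MDF for every configured method on one noisy realization.
# A single Burg recursion to the maximum order serves all orders.
estimate_cell_features <- function(y, cfg) {
  out <- matrix(NA_real_, nrow = length(cfg$methods), ncol = 2L,
                dimnames = list(cfg$methods, c("mnf", "mdf")))
  if ("welch" %in% cfg$methods) {
    p <- welch_psd(y, taper = cfg$taper)
    out["welch", ] <- c(mnf(p), mdf(p))
  }
  orders <- burg_orders(cfg$methods)
  if (length(orders)) {
    xc <- y$samples - mean(y$samples)
    rec <- burg_recursion(xc, max(orders))
    nfft <- y$n
    for (p_ord in orders) {
      model <- structure(list(order = p_ord, a = rec$a[[p_ord]],
                              sigma2 = rec$E[p_ord], n = y$n, f_s = y$f_s),
                         class = "burg")
      ps <- burg_psd(model, f_s = y$f_s, nfft = nfft)
      out[paste0("burg", p_ord), ] <- c(mnf(ps), mdf(ps))
    }
  }
  out
}

#' Run the factorial Monte-Carlo grid
#'
#' For every (duration, SNR, realization) cell a clean signal is coloured
#' from a seeded white-noise stream, measurement noise is added from an
#' independent seeded stream, every configured estimator is applied, and
#' MNF/MDF are extracted.  Errors are measured against the analytic
#' reference of \code{\link{ideal_reference}}.  The whole table is
#' reproducible from the master seed, cell by cell.
#'
#' @param config a \code{\link{study_config}}.
#' @param progress print a line per (duration, SNR) cell.
#' @return An object of class \code{semg_study}: list with
#'   \describe{
#'     \item{records}{long-format data frame: \code{method},
#'       \code{duration_ms}, \code{snr_db}, \code{realization},
#'       \code{mnf}, \code{mdf}, signed biases \code{mnf_bias}/\code{mdf_bias}
#'       (estimate minus reference) and absolute errors
#'       \code{mnf_err}/\code{mdf_err}.}
#'     \item{reference}{the \code{\link{ideal_reference}} row used as
#'       ground truth.}
#'     \item{config}{the configuration.}
#'     \item{failures}{per-cell estimator failure counts (a cell is flagged
#'       when more than 1\% of its realizations fail).}
#'   }
#' @examples
#' cfg <- study_config(durations_ms = 250, snr_db = 10, realizations = 5,
#'                     methods = c("welch", "burg3"))
#' st <- run_grid(cfg)
#' head(st$records)
#' @export
run_grid <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "study_config"))
  ref <- ideal_reference(config$f_l, config$f_h, config$f_s,
                         config$grid_step, config$k)
  n_meth <- length(config$methods)
  cells <- expand.grid(duration_ms = config$durations_ms,
                       snr_db = config$snr_db, KEEP.OUT.ATTRS = FALSE)
  chunks <- vector("list", nrow(cells))
  failures <- data.frame()
  for (ci in seq_len(nrow(cells))) {
    t_ms <- cells$duration_ms[ci]
    snr <- cells$snr_db[ci]
    t_idx <- match(t_ms, config$durations_ms)
    s_idx <- match(snr, config$snr_db)
    n <- as.integer(round(t_ms * config$f_s / 1000))
    filt <- study_filter(config, n)
    vals <- array(NA_real_, c(config$realizations, n_meth, 2L))
    n_fail <- 0L
    for (c_i in seq_len(config$realizations)) {
      res <- tryCatch({
        x <- semg_clean(t_ms, filt,
                        seed = mix_seed(config$master_seed, t_idx, c_i, 1L),
                        realization = c_i)
        y <- semg_add_noise(x, snr,
                            seed = mix_seed(config$master_seed, t_idx, s_idx, c_i, 2L))
        estimate_cell_features(y, config)
      }, error = function(e) NULL)
      if (is.null(res)) n_fail <- n_fail + 1L else vals[c_i, , ] <- res
    }
    if (n_fail > 0L)
      failures <- rbind(failures,
                        data.frame(duration_ms = t_ms, snr_db = snr,
                                   n_failed = n_fail,
                                   flagged = n_fail > 0.01 * config$realizations))
    chunks[[ci]] <- data.frame(
      method = rep(config$methods, each = config$realizations),
      duration_ms = t_ms, snr_db = snr,
      realization = rep(seq_len(config$realizations), times = n_meth),
      mnf = as.vector(vals[, , 1L]), mdf = as.vector(vals[, , 2L]))
    if (progress)
      message(sprintf("cell T=%g ms, SNR=%g dB done (%d/%d)",
                      t_ms, snr, ci, nrow(cells)))
  }
  records <- do.call(rbind, chunks)
  records$mnf_bias <- records$mnf - ref$mnf
  records$mdf_bias <- records$mdf - ref$mdf
  records$mnf_err <- abs(records$mnf_bias)
  records$mdf_err <- abs(records$mdf_bias)
  structure(list(records = records, reference = ref, config = config,
                 failures = failures),
            class = "semg_study")
}

# per-duration shaping filter; cached only for the default spectrum
study_filter <- function(config, n) {
  n_taps <- max(64L, min(n, 512L))
  if (config$k == 1 && config$f_l == 20 && config$f_h == 40 && config$f_s == 1024)
    return(cached_default_filter(n_taps))
  shaping_filter(ideal_spectrum(config$k, config$f_l, config$f_h, config$f_s),
                 n_taps = n_taps)
}

#' @export
print.semg_study <- function(x, ...) {
  r <- x$records
  cat(sprintf("sEMG estimator study: %d records (%d methods x %d durations x %d SNRs x %d realizations)\n",
              nrow(r), length(unique(r$method)), length(unique(r$duration_ms)),
              length(unique(r$snr_db)), x$config$realizations))
  cat(sprintf("  reference: MNF %.2f Hz, MDF %.2f Hz\n",
              x$reference$mnf, x$reference$mdf))
  if (nrow(x$failures)) {
    cat("  failures:\n"); print(x$failures)
  }
  invisible(x)
}

#' @export
summary.semg_study <- function(object, ...) {
  list(mnf = mae_summary(object, "mnf"), mdf = mae_summary(object, "mdf"))
}

#' Per-condition mean absolute error summary
#'
#' For every (method, duration, SNR) condition computes the mean absolute
#' error \eqn{\mathrm{MAE} = \frac1C \sum_c |y_d - y_c|} of the chosen
#' spectral parameter against the analytic reference, together with the
#' standard deviation of the absolute error, the signed mean bias, and the
#' number of realizations.
#'
#' @param study a \code{\link{run_grid}} result (or its \code{records}
#'   data frame, in which case errors must already be present).
#' @param parameter \code{"mnf"} or \code{"mdf"}.
#' @return Data frame with columns \code{method}, \code{duration_ms},
#'   \code{snr_db}, \code{mae}, \code{sd}, \code{bias}, \code{n}.
#' @export
mae_summary <- function(study, parameter = c("mnf", "mdf")) {
  parameter <- match.arg(parameter)
  records <- if (inherits(study, "semg_study")) study$records else study
  err <- paste0(parameter, "_err")
  bias <- paste0(parameter, "_bias")
  if (!err %in% names(records)) stop("no error column '", err, "' in the table")
  if (nrow(records) == 0L) stop("empty study table")
  key <- list(method = records$method, duration_ms = records$duration_ms,
              snr_db = records$snr_db)
  agg <- aggregate(records[[err]], by = key, FUN = function(v) {
    c(mae = mean(v, na.rm = TRUE), sd = sd(v, na.rm = TRUE),
      n = sum(!is.na(v)))
  })
  out <- data.frame(agg[1:3], agg$x)
  b <- aggregate(records[[bias]], by = key, FUN = mean, na.rm = TRUE)
  out$bias <- b$x[match(paste(out$method, out$duration_ms, out$snr_db),
                        paste(b$method, b$duration_ms, b$snr_db))]
  out <- out[order(out$snr_db, out$duration_ms, out$method),
             c("method", "duration_ms", "snr_db", "mae", "sd", "bias", "n")]
  empty <- out$n == 0
  if (any(empty))
    warning(sum(empty), " empty condition(s) in the MAE summary")
  rownames(out) <- NULL
  out
}

#' @export
plot.semg_study <- function(x, parameter = c("mnf", "mdf"),
                            snr_db = x$config$snr_db[1L],
                            duration_ms = x$config$durations_ms[1L], ...) {
  parameter <- match.arg(parameter)
  s <- mae_summary(x, parameter)
  s <- s[s$snr_db == snr_db & s$duration_ms == duration_ms, ]
  bp <- barplot(s$mae, names.arg = s$method, las = 2,
                ylab = sprintf("%s MAE (Hz)", toupper(parameter)),
                main = sprintf("T = %g ms, SNR = %g dB", duration_ms, snr_db), ...)
  invisible(bp)
}
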