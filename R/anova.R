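#' Balanced factorial ANOVA on per-realization errors
#'
#' Full-factorial decomposition (all main effects, all interactions,
#' residual) of a response over the named factors, computed with
#' \code{stats::aov}.  The design must be complete and balanced -- as the
#' simulated study grid always is -- so the Type-I sums of squares are
#' unambiguous and add up to the total.
#'
#' @param table a \code{\link{run_grid}} result or its \code{records}
#'   data frame.
#' @param response response column, typically \code{"mnf_err"} or
#'   \code{"mdf_err"} (the per-realization absolute errors).
#' @param factors character vector of factor columns, subset of
#'   \code{c("method", "duration_ms", "snr_db")}.
#' @return An object of class \code{semg_anova}: list with \code{table}
#'   (Source, Df, Sum Sq, Mean Sq, F, p, significance stars), the factors,
#'   and the underlying \code{aov} fit.
#' @export
factorial_anova <- function(table, response, factors) {
  records <- if (inherits(table, "semg_study")) table$records else table
  if (!response %in% names(records)) stop("unknown response column '", response, "'")
  if (!all(factors %in% names(records)))
    stop("unknown factor column(s): ",
         paste(setdiff(factors, names(records)), collapse = ", "))
  dat <- records[stats::complete.cases(records[c(response, factors)]), , drop = FALSE]
  for (f in factors) dat[[f]] <- factor(dat[[f]])
  counts <- table(dat[factors])
  if (length(unique(as.vector(counts))) != 1L || any(counts == 0))
    stop("unbalanced design: every factor-level combination must have the same number of observations")
  form <- stats::as.formula(paste(response, "~", paste(factors, collapse = " * ")))
  fit <- aov(form, data = dat)
  s <- summary(fit)[[1L]]
  src <- trimws(rownames(s))
  src[src == "Residuals"] <- "Error"
  tab <- data.frame(source = src, df = s[["Df"]], sum_sq = s[["Sum Sq"]],
                    mean_sq = s[["Mean Sq"]], f = s[["F value"]],
                    p = s[["Pr(>F)"]], stringsAsFactors = FALSE)
  tab$signif <- signif_stars(tab$p)
  structure(list(table = tab, response = response, factors = factors,
                 fit = fit, data = dat),
            class = "semg_anova")
}

signif_stars <- function(p) {
  ifelse(is.na(p), "",
         ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
                ifelse(p < 0.05, "*", ""))))
}

#' @export
print.semg_anova <- function(x, ...) {
  cat(sprintf("%d-way ANOVA on %s (factors: %s)\n",
              length(x$factors), x$response, paste(x$factors, collapse = ", ")))
  tab <- x$table
  tab$sum_sq <- signif(tab$sum_sq, 4)
  tab$mean_sq <- signif(tab$mean_sq, 4)
  tab$f <- signif(tab$f, 4)
  tab$p <- signif(tab$p, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}

# p-value of a named source term (interaction terms use aov's "a:b" naming)
anova_p <- function(an, source) {
  i <- match(source, an$table$source)
  if (is.na(i)) NA_real_ else an$table$p[i]
}

#' Tukey HSD post-hoc comparisons
#'
#' All pairwise mean differences between the levels of one factor with
#' studentized-range adjusted p-values (\code{stats::TukeyHSD}) and
#' significance flags at the 0.05 / 0.01 / 0.001 levels.
#'
#' @inheritParams factorial_anova
#' @param factor_name the factor whose levels are compared (needs >= 2
#'   levels with >= 2 observations each, balanced).
#' @return Data frame with columns \code{pair}, \code{diff}, \code{lwr},
#'   \code{upr}, \code{p_adj}, \code{signif}.
#' @export
tukey_hsd <- function(table, response, factor_name = "method") {
  records <- if (inherits(table, "semg_study")) table$records else table
  dat <- records[stats::complete.cases(records[c(response, factor_name)]), , drop = FALSE]
  dat[[factor_name]] <- factor(dat[[factor_name]])
  n_lev <- nlevels(dat[[factor_name]])
  if (n_lev < 2L) stop("need at least two groups for post-hoc comparison")
  if (min(table(dat[[factor_name]])) < 2L) stop("each group needs at least 2 observations")
  fit <- aov(stats::as.formula(paste(response, "~", factor_name)), data = dat)
  th <- TukeyHSD(fit)[[factor_name]]
  out <- data.frame(pair = rownames(th), diff = th[, "diff"],
                    lwr = th[, "lwr"], upr = th[, "upr"],
                    p_adj = th[, "p adj"], stringsAsFactors = FALSE)
  out$signif <- signif_stars(out$p_adj)
  rownames(out) <- NULL
  out
}

#' Nested ANOVA cascade over the study factors
#'
#' Implements the study's decision tree on the per-realization absolute
#' errors: a three-way ANOVA over method, duration and SNR; when the
#' three-way interaction is significant, a two-way (method x duration)
#' ANOVA at each SNR level; when that interaction is significant in turn,
#' one-way ANOVAs on method at each duration.  Whenever a method effect is
#' significant, Tukey HSD post-hoc comparisons between methods are
#' attached.  When the higher-order interactions are not significant the
#' cascade falls through to a direct one-way ANOVA on method.
#'
#' @inheritParams factorial_anova
#' @param alpha significance threshold steering the cascade (default 0.05).
#' @return An object of class \code{semg_cascade}: list with
#'   \code{three_way}, \code{two_way} (per SNR), \code{one_way} (per
#'   SNR/duration slice or pooled), and \code{posthoc} (Tukey tables keyed
#'   like \code{one_way}).
#' @export
anova_cascade <- function(table, response, alpha = 0.05) {
  records <- if (inherits(table, "semg_study")) table$records else table
  # reduced grids (a single duration or SNR level) cannot support the full
  # three-way decomposition; fall back to a direct one-way on method
  multi <- vapply(c("duration_ms", "snr_db"),
                  function(f) length(unique(records[[f]])) > 1L, logical(1))
  if (!all(multi)) {
    out <- list(three_way = NULL, two_way = list(), one_way = list(),
                posthoc = list(), alpha = alpha, response = response)
    an1 <- factorial_anova(records, response, "method")
    out$one_way[["pooled"]] <- an1
    if (isTRUE(anova_p(an1, "method") < alpha))
      out$posthoc[["pooled"]] <- tukey_hsd(records, response, "method")
    return(structure(out, class = "semg_cascade"))
  }
  three <- factorial_anova(records, response, c("method", "duration_ms", "snr_db"))
  out <- list(three_way = three, two_way = list(), one_way = list(),
              posthoc = list(), alpha = alpha, response = response)
  p3 <- anova_p(three, "method:duration_ms:snr_db")

  one_way_at <- function(dat, key) {
    an1 <- factorial_anova(dat, response, "method")
    out$one_way[[key]] <<- an1
    if (isTRUE(anova_p(an1, "method") < alpha))
      out$posthoc[[key]] <<- tukey_hsd(dat, response, "method")
  }

  if (isTRUE(p3 < alpha)) {
    for (s in sort(unique(records$snr_db))) {
      slice_s <- records[records$snr_db == s, ]
      an2 <- factorial_anova(slice_s, response, c("method", "duration_ms"))
      out$two_way[[paste0("snr_", s)]] <- an2
      if (isTRUE(anova_p(an2, "method:duration_ms") < alpha)) {
        for (d in sort(unique(slice_s$duration_ms)))
          one_way_at(slice_s[slice_s$duration_ms == d, ],
                     paste0("snr_", s, "_dur_", d))
      } else {
        one_way_at(slice_s, paste0("snr_", s))
      }
    }
  } else {
    one_way_at(records, "pooled")
  }
  structure(out, class = "semg_cascade")
}

#' @export
print.semg_cascade <- function(x, ...) {
  cat("ANOVA cascade on", x$response, "\n\n")
  if (is.null(x$three_way)) {
    cat("reduced design: direct one-way ANOVA on method\n")
  } else {
    print(x$three_way)
    p3 <- anova_p(x$three_way, "method:duration_ms:snr_db")
    cat(sprintf("\nthree-way interaction p = %.3g (%s at alpha = %g)\n",
                p3, if (isTRUE(p3 < x$alpha)) "significant" else "not significant",
                x$alpha))
  }
  if (length(x$two_way)) {
    cat(sprintf("two-way ANOVAs at %d SNR levels; one-way method ANOVAs in %d slices; %d post-hoc tables\n",
                length(x$two_way), length(x$one_way), length(x$posthoc)))
  } else {
    cat(sprintf("direct one-way method ANOVA (%d slices), %d post-hoc tables\n",
                length(x$one_way), length(x$posthoc)))
  }
  invisible(x)
}
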