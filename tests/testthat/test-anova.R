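# Factorial ANOVA wrapper, Tukey HSD, and the nested cascade.

balanced_table <- function(methods = c("w", "b3", "b15"), durations = c(250, 500),
                           snrs = c(5, 20), C = 20, seed = 1,
                           method_shift = 0) {
  set.seed(seed)
  tab <- expand.grid(method = methods, duration_ms = durations, snr_db = snrs,
                     realization = seq_len(C), stringsAsFactors = FALSE)
  shift <- method_shift * (match(tab$method, methods) - 1)
  tab$mnf_err <- abs(rnorm(nrow(tab)) + shift)
  tab
}

test_that("one-way F on two groups equals the squared pooled t statistic", {
  toy <- data.frame(method = rep(c("a", "b"), each = 3),
                    mnf_err = c(3.1, 2.7, 3.4, 4.0, 4.4, 3.9))
  an <- factorial_anova(toy, "mnf_err", "method")
  tt <- t.test(mnf_err ~ method, data = toy, var.equal = TRUE)
  expect_equal(an$table$f[1], unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(an$table$p[1], tt$p.value, tolerance = 1e-10)
  # hand check of the group sum of squares: n per group * sum (mean_g - mean)^2
  means <- tapply(toy$mnf_err, toy$method, mean)
  ss_between <- 3 * sum((means - mean(toy$mnf_err))^2)
  expect_equal(an$table$sum_sq[1], ss_between, tolerance = 1e-10)
})

test_that("sums of squares add up on balanced tables", {
  tab <- balanced_table(C = 10)
  an <- factorial_anova(tab, "mnf_err", c("method", "duration_ms", "snr_db"))
  total <- sum((tab$mnf_err - mean(tab$mnf_err))^2)
  expect_lt(abs(sum(an$table$sum_sq) - total) / total, 1e-8)
  expect_equal(nrow(an$table), 8)      # 3 mains + 3 two-way + 1 three-way + error
})

test_that("constant response yields zero effect sums of squares", {
  tab <- balanced_table(C = 5)
  tab$mnf_err <- 2.5
  an <- factorial_anova(tab, "mnf_err", c("method", "duration_ms"))
  eff <- an$table$sum_sq[an$table$source != "Error"]
  expect_true(all(abs(eff) < 1e-20))
})

test_that("unbalanced designs are rejected", {
  tab <- balanced_table(C = 5)
  expect_error(factorial_anova(tab[-1, ], "mnf_err", c("method", "duration_ms", "snr_db")),
               "unbalanced")
})

test_that("an injected method-only effect is detected and nothing else", {
  tab <- balanced_table(methods = c("w", "b3", "b15"), C = 100, seed = 5,
                        method_shift = 0.5)
  an <- factorial_anova(tab, "mnf_err", c("method", "duration_ms", "snr_db"))
  p <- setNames(an$table$p, an$table$source)
  expect_lt(p[["method"]], 0.001)
  others <- p[setdiff(names(p), c("method", "Error"))]
  expect_true(all(others > 0.001, na.rm = TRUE))
})

test_that("Tukey HSD behaves at its boundary cases", {
  # two near-identical groups: adjusted p close to 1
  set.seed(31)
  g <- rnorm(40)
  tab <- data.frame(method = rep(c("a", "b"), each = 20), mnf_err = c(g[1:20], g[1:20]))
  th <- tukey_hsd(tab, "mnf_err", "method")
  expect_gt(th$p_adj[1], 0.97)

  # with exactly two groups the studentized range collapses to the t test
  set.seed(32)
  tab2 <- data.frame(method = rep(c("a", "b"), each = 15),
                     mnf_err = c(rnorm(15), rnorm(15, mean = 0.6)))
  th2 <- tukey_hsd(tab2, "mnf_err", "method")
  tt <- t.test(mnf_err ~ method, data = tab2, var.equal = TRUE)
  expect_equal(th2$p_adj[1], tt$p.value, tolerance = 1e-6)

  # one clearly shifted group: all its pairs significant
  set.seed(33)
  tab3 <- data.frame(method = rep(c("a", "b", "c"), each = 20),
                     mnf_err = c(rnorm(40, sd = 0.2), rnorm(20, mean = 5, sd = 0.2)))
  th3 <- tukey_hsd(tab3, "mnf_err", "method")
  c_pairs <- grepl("c", th3$pair)
  expect_true(all(th3$p_adj[c_pairs] < 0.001))
  expect_true(th3$p_adj[!c_pairs] > 0.05)

  expect_error(tukey_hsd(data.frame(method = "a", mnf_err = 1:5), "mnf_err", "method"),
               "two groups")
})

test_that("cascade on a constant response stops at a single quiet one-way", {
  tab <- balanced_table(C = 5)
  tab$mnf_err <- 1
  casc <- anova_cascade(tab, "mnf_err")
  expect_length(casc$two_way, 0)
  expect_named(casc$one_way, "pooled")
  expect_length(casc$posthoc, 0)
})

test_that("cascade descends on a response with a three-way interaction", {
  # build an interaction by hand: method effect flips sign with duration,
  # and does so only at one SNR level
  tab <- balanced_table(methods = c("w", "b3"), durations = c(250, 2000),
                        snrs = c(5, 20), C = 60, seed = 8)
  inter <- with(tab, (method == "b3") * (duration_ms == 2000) * (snr_db == 5))
  tab$mnf_err <- abs(rnorm(nrow(tab)) + 2 * inter)
  casc <- anova_cascade(tab, "mnf_err")
  expect_gt(length(casc$two_way), 0)
  expect_gt(length(casc$one_way), 0)
  expect_gt(length(casc$posthoc), 0)
})
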