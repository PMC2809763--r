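test_that("Welch test from the printed summaries matches the reported p-value", {
  ht <- welch_t_summary(wt_summary(), mut_summary(), "greater")
  expect_equal(unname(ht$statistic), 4.944980, tolerance = 1e-6)
  expect_equal(unname(ht$parameter), 10.945171, tolerance = 1e-6)
  expect_equal(ht$p.value, 2.2284e-4, tolerance = 1e-4)
  # pooled variant differs (about 1.1e-4), Welch stays the default
  pooled <- welch_t_summary(wt_summary(), mut_summary(), "greater",
                            pooled = TRUE)
  expect_equal(unname(pooled$parameter), 14)
  expect_lt(pooled$p.value, ht$p.value)
})

test_that("summary-based t and F tests agree exactly with raw-data routines", {
  set.seed(1618)
  for (i in 1:10) {
    na <- sample(3:12, 1); nb <- sample(3:12, 1)
    a <- summary_stats(runif(1, 10, 100), runif(1, 1, 15), na)
    b <- summary_stats(runif(1, 10, 100), runif(1, 1, 15), nb)
    xa <- rescale_to_summary(rnorm(na), a$mean, a$sd)
    xb <- rescale_to_summary(rnorm(nb), b$mean, b$sd)
    tt <- t.test(xb, xa, alternative = "greater", var.equal = FALSE)
    ht <- welch_t_summary(a, b, "greater")
    expect_equal(unname(ht$statistic), unname(tt$statistic),
                 tolerance = 1e-10)
    expect_equal(ht$p.value, tt$p.value, tolerance = 1e-10)
    # pooled route against var.equal = TRUE
    tp <- t.test(xb, xa, alternative = "greater", var.equal = TRUE)
    hp <- welch_t_summary(a, b, "greater", pooled = TRUE)
    expect_equal(hp$p.value, tp$p.value, tolerance = 1e-10)
    # F test against var.test
    vt <- var.test(xa, xb, alternative = "greater")
    hf <- variance_ratio_test(a, b, "greater")
    expect_equal(unname(hf$statistic), unname(vt$statistic),
                 tolerance = 1e-10)
    expect_equal(hf$p.value, vt$p.value, tolerance = 1e-10)
    # two-sided CI against t.test's interval
    ci <- mean_diff_ci_summary(a, b, 0.95, sided = "two")
    tt2 <- t.test(xb, xa, conf.level = 0.95)
    expect_equal(c(ci$lower, ci$upper), as.vector(tt2$conf.int),
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("identical groups give t = 0 with one-sided p one half", {
  s <- summary_stats(50, 6, 8)
  ht <- welch_t_summary(s, s, "greater")
  expect_equal(unname(ht$statistic), 0)
  expect_equal(ht$p.value, 0.5)
  # degenerate zero-sd pair
  z <- summary_stats(10, 0, 5)
  hz <- welch_t_summary(z, z, "greater")
  expect_equal(hz$p.value, 0.5)
  expect_match(hz$method, "degenerate")
  expect_equal(welch_t_summary(z, z, "two.sided")$p.value, 1)
})

test_that("one-sided p-values are complementary and exchange-symmetric", {
  set.seed(31415)
  for (i in 1:20) {
    a <- summary_stats(runif(1, 1, 50), runif(1, 0.5, 9), sample(2:20, 1))
    b <- summary_stats(runif(1, 1, 50), runif(1, 0.5, 9), sample(2:20, 1))
    pg <- welch_t_summary(a, b, "greater")$p.value
    pl <- welch_t_summary(a, b, "less")$p.value
    expect_equal(pg + pl, 1, tolerance = 1e-12)
    expect_equal(pg, welch_t_summary(b, a, "less")$p.value,
                 tolerance = 1e-12)
    fg <- variance_ratio_test(a, b, "greater")$p.value
    fl <- variance_ratio_test(a, b, "less")$p.value
    expect_equal(fg + fl, 1, tolerance = 1e-12)
    expect_equal(fg, variance_ratio_test(b, a, "less")$p.value,
                 tolerance = 1e-12)
    # Welch df within [min(n)-1, n_a+n_b-2]
    df <- unname(welch_t_summary(a, b)$parameter)
    expect_gte(df, min(a$n, b$n) - 1 - 1e-9)
    expect_lte(df, a$n + b$n - 2 + 1e-9)
  }
  # equal sds and ns collapse Welch onto the pooled test
  a <- summary_stats(10, 3, 9); b <- summary_stats(12, 3, 9)
  expect_equal(unname(welch_t_summary(a, b)$parameter), 16)
  expect_equal(welch_t_summary(a, b)$p.value,
               welch_t_summary(a, b, pooled = TRUE)$p.value,
               tolerance = 1e-12)
})

test_that("one-sided confidence bound reproduces the reported 11-Inf interval", {
  ci <- mean_diff_ci_summary(wt_summary(), mut_summary(), 0.95, "one")
  expect_equal(ci$lower, 11.459883, tolerance = 1e-5)
  expect_equal(round(ci$lower), 11)
  expect_identical(ci$upper, Inf)
  # zero effect: the bound is negative
  s <- summary_stats(50, 6, 8)
  expect_lt(mean_diff_ci_summary(s, s)$lower, 0)
  expect_error(mean_diff_ci_summary(s, s, confidence = 1), "\\(0, 1\\)")
})

test_that("one-sided bound and one-sided test reject together (duality)", {
  set.seed(92653)
  for (i in 1:30) {
    a <- summary_stats(runif(1, 10, 60), runif(1, 1, 10), sample(3:15, 1))
    b <- summary_stats(runif(1, 10, 60), runif(1, 1, 10), sample(3:15, 1))
    rejects <- welch_t_summary(a, b, "greater")$p.value < 0.05
    bound_pos <- mean_diff_ci_summary(a, b, 0.95, "one")$lower > 0
    expect_identical(rejects, bound_pos)
  }
})

test_that("variance-ratio test recomputes the homogeneity check exactly", {
  hf <- variance_ratio_test(wt_summary(), mut_summary(), "greater")
  expect_equal(unname(hf$statistic), 81 / 25)
  expect_equal(unname(hf$parameter), c(7, 7))
  # exact one-sided p is about 0.072, not the rounded 0.1 sometimes quoted
  expect_equal(hf$p.value, 0.0718542, tolerance = 1e-5)
  # equal sds: F = 1, one-sided p exactly one half at equal df
  e <- summary_stats(10, 4, 8)
  expect_equal(variance_ratio_test(e, e, "greater")$p.value, 0.5)
  expect_error(variance_ratio_test(summary_stats(1, 0, 5), e), "group a")
  expect_error(variance_ratio_test(e, summary_stats(1, 0, 5)), "group b")
})

test_that("variance-ratio one-sided p matches a Monte-Carlo null oracle and is alpha-calibrated", {
  # oracle: variance ratios of two n = 8 normal samples under the null
  set.seed(58979)
  R <- 20000
  va <- matrix(rnorm(8 * R), 8)
  vb <- matrix(rnorm(8 * R), 8)
  ratio <- apply(va, 2, var) / apply(vb, 2, var)
  # tail beyond the observed 81/25 reproduces the analytic p
  p_mc <- mean(ratio > 81 / 25)
  p_exact <- variance_ratio_test(wt_summary(), mut_summary(),
                                 "greater")$p.value
  expect_lt(abs(p_mc - p_exact), 3 * sqrt(p_exact * (1 - p_exact) / R))
  # type-I calibration at alpha = 0.05
  crit <- qf(0.95, 7, 7)
  rate <- mean(ratio > crit)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / R))
})
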