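test_that("analytic moments follow the binomial formulas", {
  mom <- expected_moments(100, 5, 10)
  expect_equal(mom$mean, 50)
  expect_equal(mom$variance, 25)
  # h = L: deterministic crossing
  mom <- expected_moments(42, 10, 10)
  expect_equal(mom$mean, 42)
  expect_equal(mom$variance, 0)
  # Poisson limit: variance equals mean, close to binomial when h << L
  pois <- expected_moments(100, 0.5, 100, approx = "poisson")
  expect_equal(pois$variance, pois$mean)
  expect_equal(pois$variance,
               expected_moments(100, 0.5, 100)$variance, tolerance = 0.01)
  expect_error(expected_moments(10, 11, 10), "\\(0, L")
  expect_error(expected_moments(10, 0, 10), "\\(0, L")
  expect_error(expected_moments(-1, 5, 10), "non-negative")
})

test_that("moment fit inverts the moment equations exactly (round trip)", {
  set.seed(2718)
  for (i in 1:50) {
    L <- runif(1, 10, 500)
    h <- runif(1, 0.01, 0.99) * L
    m <- runif(1, 1, 500)
    mom <- expected_moments(m, h, L)
    fit <- fit_moments(mom$mean, mom$variance, L)
    expect_true(fit$feasible)
    expect_equal(fit$m_hat, m, tolerance = 1e-9)
    expect_equal(fit$h_hat, h, tolerance = 1e-9)
    # algebraic round trip through the forward map
    back <- expected_moments(fit$m_hat, fit$h_hat, L)
    expect_equal(back$mean, mom$mean, tolerance = 1e-9)
    expect_equal(back$variance, mom$variance, tolerance = 1e-9)
  }
})

test_that("feasibility exactly characterises variance < mean", {
  # printed wild-type summaries: variance 81 exceeds mean 67
  fit <- fit_moments(67, 81, L = 100)
  expect_false(fit$feasible)
  expect_lt(fit$p_hat, 0)
  expect_match(fit$diagnosis, "overdispersed")
  expect_true(is.na(fit$m_hat))
  # boundary: zero variance implies h = L, degenerate
  expect_false(fit_moments(50, 0, L = 100)$feasible)
  expect_false(fit_moments(50, 50, L = 100)$feasible)
  expect_true(fit_moments(50, 49.9, L = 100)$feasible)
  expect_error(fit_moments(0, 10), "positive")
  # mutant-side printed summaries are feasible and match the known fit
  fit <- fit_moments(85, 25, L = 100)
  expect_true(fit$feasible)
  expect_equal(fit$p_hat, 12 / 17, tolerance = 1e-12)
  expect_equal(fit$m_hat, 85 * 17 / 12, tolerance = 1e-12)
  expect_equal(fit$h_hat, 1200 / 17, tolerance = 1e-12)
})

test_that("moment fit recovers (m, h) from large simulated samples", {
  m <- 120; h <- 70; L <- 100
  d <- simulate_experiment(mt_set(m = m, h = h), axon_geometry(L),
                           section_plan("random", 10000), seed = 31)
  fit <- fit_moments(mean(d$count), var(d$count), L)
  expect_true(fit$feasible)
  expect_lt(abs(fit$m_hat - m) / m, 0.05)
  expect_lt(abs(fit$h_hat - h) / h, 0.05)
})

test_that("number-only change scales the predicted variance linearly in the mean", {
  ref <- summary_stats(67, 9, 8)
  expect_equal(predict_variance_number_only(ref, 85), 81 * 85 / 67)
  expect_equal(predict_variance_number_only(ref, 67), 81)
  # linearity
  v1 <- predict_variance_number_only(ref, 10)
  v2 <- predict_variance_number_only(ref, 20)
  expect_equal(v2, 2 * v1)
  expect_error(predict_variance_number_only(summary_stats(0, 1, 8), 10),
               "positive")
})

test_that("doubling m at fixed h doubles the empirical count variance", {
  L <- 100; h <- 50
  v <- sapply(c(60, 120), function(m) {
    d <- simulate_experiment(mt_set(m = m, h = h), axon_geometry(L),
                             section_plan("random", 8000), seed = 77)
    var(d$count)
  })
  # analytic variances 15 and 30; MC SE of each s^2 about var*sqrt(2/n)
  expect_lt(abs(v[2] / v[1] - 2), 4 * 2 * sqrt(2 / 7999) * sqrt(2))
})

test_that("discrimination reproduces the length-favored inference on the printed summaries", {
  d <- discriminate_change(wt_summary(), mut_summary(), alpha = 0.05)
  expect_identical(d$verdict, "length-favored")
  expect_true(d$product_inequality)
  expect_equal(d$predicted_variance_number_only, 81 * 85 / 67)
  expect_lt(d$mean_test$p.value, 0.05)
  # the one-sided F test finds no support for the variance increase a
  # number-only change would require
  expect_gt(d$variance_test$p.value, 0.05)
})

test_that("discrimination returns no-change for identical or non-significant groups", {
  s <- summary_stats(70, 8, 8)
  d <- discriminate_change(s, s)
  expect_identical(d$verdict, "no-change")
  expect_false(d$product_inequality)
  # degenerate: both sds zero, equal means
  z <- summary_stats(10, 0, 8)
  d0 <- discriminate_change(z, z)
  expect_identical(d0$verdict, "no-change")
  expect_match(d0$note, "degenerate")
})

test_that("swapping groups with the reversed alternative mirrors the verdict", {
  d1 <- discriminate_change(wt_summary(), mut_summary(),
                            alternative = "greater")
  d2 <- discriminate_change(mut_summary(), wt_summary(),
                            alternative = "less")
  expect_identical(d1$verdict, d2$verdict)
  expect_equal(d1$mean_test$p.value, d2$mean_test$p.value)
})

test_that("a pure number change is read as number-consistent in most end-to-end replicates", {
  L <- 100; h <- 50
  base <- scenario_config("a", 100, list(kind = "fixed", m = 60),
                          list(kind = "fixed", h = h), L = L)
  doubled <- scenario_config("b", 100, list(kind = "fixed", m = 120),
                             list(kind = "fixed", h = h), L = L)
  verdicts <- sapply(1:40, function(r) {
    ca <- generate_counts(base, seed = derive_seed(1404, 2 * r))
    cb <- generate_counts(doubled, seed = derive_seed(1404, 2 * r + 1))
    sa <- summarize_counts(ca, by = NULL)
    sb <- summarize_counts(cb, by = NULL)
    discriminate_change(summary_stats(sa$mean, sa$sd, sa$n),
                        summary_stats(sb$mean, sb$sd, sb$n))$verdict
  })
  expect_gt(mean(verdicts == "number-consistent"), 0.5)
})

test_that("power simulation is calibrated under the null and reports frequencies", {
  sc <- alm_scenario_pair()
  # identical scenarios: mean-difference rejections at about alpha
  null <- power_simulation(sc$wt, sc$wt, reps = 600, alpha = 0.05,
                           seed = 2026)
  p_sig <- attr(null, "prop_mean_significant")
  expect_lt(abs(p_sig - 0.05), 3 * sqrt(0.05 * 0.95 / 600))
  expect_equal(sum(null$frequency), 1)
  # the reference-condition design mostly reaches length-favored
  alt <- power_simulation(sc$wt, sc$elpc1, reps = 150, seed = 2027)
  expect_gt(alt$frequency[alt$verdict == "length-favored"], 0.5)
  expect_gt(attr(alt, "prop_mean_significant"), 0.5)
})
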