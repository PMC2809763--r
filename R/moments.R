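#' Analytic count moments of the fixed-m stick model
#'
#' With `m` microtubules of fixed length `h` placed uniformly in an axon
#' of length `L` (circular convention), the intersection count at any
#' section is Binomial(`m`, `p = h/L`), so
#' `E(X) = m h / L` and `Var(X) = m h / L (1 - h / L)`.
#'
#' A count narrative sometimes treats X as Poisson; that is the small-
#' crossing-probability limit of the binomial (`h << L`), where the
#' variance approaches the mean.  `approx = "poisson"` returns that
#' limiting pair `(m h / L, m h / L)`; the binomial form is exact for the
#' model and is the default.
#'
#' @param m microtubule number, `>= 0` (real-valued allowed; the moments
#'   are linear in `m`).
#' @param h microtubule length, um, in `(0, L]`.
#' @param L axon length, um, positive.
#' @param approx `"binomial"` (exact, default) or `"poisson"` (the
#'   `h << L` approximation with variance equal to the mean).
#' @return a list of class `"moment_pair"` with fields `mean`, `variance`.
#' @examples
#' expected_moments(100, 5, 10)   # mean 50, variance 25
#' @export
expected_moments <- function(m, h, L, approx = c("binomial", "poisson")) {
  approx <- match.arg(approx)
  if (!is.numeric(m) || any(m < 0))
    stop_domain("m must be non-negative")
  if (!is.numeric(L) || any(L <= 0))
    stop_domain("L must be positive")
  if (any(h <= 0) || any(h > L))
    stop_domain("h = %s must lie in (0, L = %s]",
                paste(format(h), collapse = ","),
                paste(format(L), collapse = ","))
  p <- h / L
  structure(list(mean = m * p,
                 variance = if (approx == "poisson") m * p
                            else m * p * (1 - p)),
            class = "moment_pair")
}

#' Method-of-moments fit of the stick model
#'
#' Inverts the moment equations `mean = m p`, `variance = m p (1 - p)`
#' with `p = h / L`: `p_hat = 1 - variance / mean`, and when
#' `0 < p_hat < 1` also `m_hat = mean / p_hat` and `h_hat = p_hat * L`.
#'
#' Feasibility exactly characterises `0 < variance < mean`.  A sample
#' variance at or above the sample mean is *not* an error: no fixed-m
#' independent-stick model can produce it (Poisson-binomial bound
#' `Var = sum p_i (1 - p_i) <= sum p_i = mean`), so the fit is returned
#' infeasible with an overdispersion diagnosis — the signature of
#' between-animal variation in `m`.
#'
#' @param sample_mean positive sample mean count.
#' @param sample_variance non-negative sample variance (counts squared).
#' @param L axon length, um; `NA` allowed (then `h_hat` is `NA` and only
#'   `p_hat`, `m_hat` are estimated).
#' @return an object of class `"moment_fit"`: `p_hat`, `m_hat`, `h_hat`,
#'   `feasible`, `diagnosis`.
#' @examples
#' fit_moments(85, 25, L = 100)   # feasible: m_hat ~ 120.4, h_hat ~ 70.6
#' fit_moments(67, 81, L = 100)   # infeasible: variance exceeds mean
#' @export
fit_moments <- function(sample_mean, sample_variance, L = NA_real_) {
  if (!is.numeric(sample_mean) || length(sample_mean) != 1L ||
      sample_mean <= 0)
    stop_domain("sample_mean must be a single positive number")
  if (!is.numeric(sample_variance) || length(sample_variance) != 1L ||
      sample_variance < 0)
    stop_domain("sample_variance must be non-negative")
  p_hat <- 1 - sample_variance / sample_mean
  feasible <- p_hat > 0 && p_hat < 1
  diagnosis <- if (feasible) "ok"
    else if (p_hat <= 0)
      "overdispersed relative to fixed-m model (variance >= mean)"
    else "degenerate boundary (variance = 0 implies h = L exactly)"
  structure(list(
    p_hat = p_hat,
    m_hat = if (feasible) sample_mean / p_hat else NA_real_,
    h_hat = if (feasible) p_hat * L else NA_real_,
    L = L,
    feasible = feasible,
    diagnosis = diagnosis,
    sample_mean = sample_mean,
    sample_variance = sample_variance), class = "moment_fit")
}

#' @export
print.moment_fit <- function(x, digits = 4, ...) {
  cat("Method-of-moments fit of the stick model\n")
  cat(sprintf("  input: mean = %s, variance = %s\n",
              format(x$sample_mean), format(x$sample_variance)))
  if (x$feasible) {
    cat(sprintf("  p_hat = %s  m_hat = %s  h_hat = %s um (L = %s um)\n",
                format(x$p_hat, digits = digits),
                format(x$m_hat, digits = digits),
                format(x$h_hat, digits = digits), format(x$L)))
  } else {
    cat(sprintf("  infeasible: %s (p_hat = %s)\n", x$diagnosis,
                format(x$p_hat, digits = digits)))
  }
  invisible(x)
}

#' Mutant variance implied by a number-only change
#'
#' If only the microtubule number changes (`h`, hence `p`, fixed), mean
#' and variance both scale linearly in `m`, so the variance the second
#' group must show is `ref_variance * target_mean / ref_mean`.  An
#' elevated mean with a *lower* observed variance therefore argues against
#' a pure number increase.
#'
#' @param ref a [summary_stats()] for the reference group.
#' @param target_mean the other group's mean count.
#' @return the implied variance (counts squared).
#' @examples
#' predict_variance_number_only(summary_stats(67, 9, 8), 85)  # ~102.8
#' @export
predict_variance_number_only <- function(ref, target_mean) {
  ref <- as_summary_stats(ref)
  if (ref$mean <= 0) stop_domain("reference mean must be positive")
  ref$sd^2 * target_mean / ref$mean
}

#' Discriminate "more microtubules" from "longer microtubules"
#'
#' Operationalises the variance-implication argument on two groups of
#' section counts summarised as (mean, sd, n).  The stages, all of whose
#' statistics are returned so users can apply their own rule:
#'
#' 1. One-sided Welch t-test that the `alt` group's mean count departs
#'    from `ref` in the stated direction.  Not significant at `alpha`:
#'    verdict `"no-change"`.
#' 2. If significant, the product inequality `m_alt h_alt > m_ref h_ref`
#'    (or `<` under `alternative = "less"`) follows from
#'    `E(X) = m h / L`: more microtubules, longer ones, or both.
#' 3. The number-only hypothesis (`h` unchanged, only `m` moved) pins the
#'    alt variance at [predict_variance_number_only()].  If the observed
#'    alt variance moves *against* the predicted direction (point
#'    estimate) and a one-sided variance-ratio F-test finds no support for
#'    a variance shift in the predicted direction: verdict
#'    `"length-favored"`.
#' 4. Otherwise, if the observed variance ratio lies inside a two-sided
#'    `(1 - alpha)` F acceptance band around the predicted ratio
#'    (normal-theory sampling of the two sample variances): verdict
#'    `"number-consistent"`; else `"indeterminate"`.
#'
#' @param ref,alt [summary_stats()] for the reference (e.g. wild type)
#'   and alternative (e.g. mutant) groups.
#' @param alpha one-sided significance level, default 0.05.
#' @param alternative direction of the alt-vs-ref mean hypothesis:
#'   `"greater"` (default) or `"less"`.
#' @param pooled use the pooled-df t-test instead of Welch.
#' @return an object of class `"discrimination"`: `verdict`, `mean_test`,
#'   `product_inequality`, `predicted_variance_number_only`,
#'   `variance_test`, `variance_band`, `variance_consistent`, `alpha`.
#' @examples
#' discriminate_change(summary_stats(67, 9, 8), summary_stats(85, 5, 8))
#' @export
discriminate_change <- function(ref, alt, alpha = 0.05,
                                alternative = c("greater", "less"),
                                pooled = FALSE) {
  alternative <- match.arg(alternative)
  ref <- as_summary_stats(ref); alt <- as_summary_stats(alt)
  dir <- if (alternative == "greater") 1 else -1
  mean_test <- welch_t_summary(ref, alt, alternative = alternative,
                               pooled = pooled)
  pred_var <- predict_variance_number_only(ref, alt$mean)
  res <- list(mean_test = mean_test,
              predicted_variance_number_only = pred_var,
              alpha = alpha, alternative = alternative,
              ref = ref, alt = alt)
  degenerate <- ref$sd == 0 && alt$sd == 0 && ref$mean == alt$mean
  if (degenerate || mean_test$p.value >= alpha) {
    res$verdict <- "no-change"
    res$product_inequality <- FALSE
    res$note <- if (degenerate) "degenerate: both sds zero, equal means"
    return(structure(res, class = "discrimination"))
  }
  res$product_inequality <- TRUE
  # one-sided F-test for a variance shift in the number-only direction
  var_test <- variance_ratio_test(alt, ref, alternative = alternative)
  res$variance_test <- var_test
  obs_ratio <- alt$sd^2 / ref$sd^2
  pred_ratio <- alt$mean / ref$mean      # variance ratio if only m changed
  band <- pred_ratio *
    stats::qf(c(alpha / 2, 1 - alpha / 2), alt$n - 1, ref$n - 1)
  res$variance_band <- band
  res$variance_consistent <- obs_ratio >= band[1] && obs_ratio <= band[2]
  opposite_point <- (alt$sd^2 - ref$sd^2) * dir < 0
  res$verdict <-
    if (opposite_point && var_test$p.value >= alpha) "length-favored"
    else if (res$variance_consistent) "number-consistent"
    else "indeterminate"
  structure(res, class = "discrimination")
}

#' @export
print.discrimination <- function(x, digits = 4, ...) {
  cat("Discrimination: microtubule number vs length change\n")
  cat(sprintf("  ref: mean %s, sd %s, n %d | alt: mean %s, sd %s, n %d\n",
              format(x$ref$mean), format(x$ref$sd), x$ref$n,
              format(x$alt$mean), format(x$alt$sd), x$alt$n))
  cat(sprintf("  mean test (one-sided %s, alpha = %s): t = %s, p = %s\n",
              x$alternative, format(x$alpha),
              format(x$mean_test$statistic, digits = digits),
              format(x$mean_test$p.value, digits = digits)))
  cat(sprintf("  product inequality m_alt*h_alt %s m_ref*h_ref: %s\n",
              if (x$alternative == "greater") ">" else "<",
              x$product_inequality))
  cat(sprintf("  variance if number-only change: %s (observed %s)\n",
              format(x$predicted_variance_number_only, digits = digits),
              format(x$alt$sd^2)))
  if (!is.null(x$variance_test))
    cat(sprintf("  variance-ratio test: F = %s, p = %s; band on ratio [%s, %s]\n",
                format(x$variance_test$statistic, digits = digits),
                format(x$variance_test$p.value, digits = digits),
                format(x$variance_band[1], digits = digits),
                format(x$variance_band[2], digits = digits)))
  cat(sprintf("  verdict: %s\n", x$verdict))
  invisible(x)
}

#' Monte-Carlo power analysis of the discrimination pipeline
#'
#' Repeatedly simulates two groups from their scenario configurations,
#' summarises the counts, runs [discriminate_change()], and tabulates how
#' often each verdict is reached — quantifying how reliable a design of a
#' given size (e.g. eight sections per genotype) is.
#'
#' @param scenario_ref,scenario_alt [scenario_config()]s for the two
#'   groups.
#' @param reps number of Monte-Carlo replicates.
#' @param alpha significance level passed to [discriminate_change()].
#' @param alternative direction of the alt-vs-ref hypothesis.
#' @param seed integer top-level seed; replicate `r` uses substreams
#'   derived from `derive_seed(seed, r)`.
#' @return a data frame with one row per verdict: `verdict`, `frequency`,
#'   `mc_se` (binomial Monte-Carlo standard error), plus attributes
#'   `reps` and `prop_mean_significant`.
#' @export
power_simulation <- function(scenario_ref, scenario_alt, reps = 200,
                             alpha = 0.05,
                             alternative = c("greater", "less"),
                             seed = 1L) {
  alternative <- match.arg(alternative)
  stopifnot(reps >= 1)
  verdicts <- character(reps)
  sig <- logical(reps)
  for (r in seq_len(reps)) {
    s <- derive_seed(seed, r)
    counts_ref <- generate_counts(scenario_ref, seed = derive_seed(s, 1))
    counts_alt <- generate_counts(scenario_alt, seed = derive_seed(s, 2))
    sm_ref <- summarize_counts(counts_ref, by = NULL)
    sm_alt <- summarize_counts(counts_alt, by = NULL)
    ss_ref <- summary_stats(sm_ref$mean, sm_ref$sd, sm_ref$n)
    ss_alt <- summary_stats(sm_alt$mean, sm_alt$sd, sm_alt$n)
    d <- discriminate_change(ss_ref, ss_alt, alpha = alpha,
                             alternative = alternative)
    verdicts[r] <- d$verdict
    sig[r] <- d$verdict != "no-change"
  }
  lev <- c("no-change", "number-consistent", "length-favored",
           "indeterminate")
  freq <- table(factor(verdicts, levels = lev)) / reps
  out <- data.frame(verdict = lev, frequency = as.vector(freq),
                    mc_se = sqrt(as.vector(freq) * (1 - as.vector(freq)) /
                                   reps))
  attr(out, "reps") <- reps
  attr(out, "prop_mean_significant") <- mean(sig)
  out
}
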