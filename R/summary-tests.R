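#' Summary statistics triple
#'
#' The (mean, sd, n) triple that summarises one group of section counts,
#' e.g. the printed wild-type values `summary_stats(67, 9, 8)`.
#'
#' @param mean sample mean count.
#' @param sd sample standard deviation (n - 1 denominator).
#' @param n number of sections, a positive integer (`>= 2` for any
#'   variance-based test).
#' @return an object of class `"summary_stats"`.
#' @export
summary_stats <- function(mean, sd, n) {
  stopifnot(is.numeric(mean), length(mean) == 1L, is.finite(mean),
            is.numeric(sd), length(sd) == 1L, is.finite(sd), sd >= 0,
            is.numeric(n), length(n) == 1L, n >= 1, n == as.integer(n))
  structure(list(mean = as.double(mean), sd = as.double(sd),
                 n = as.integer(n)), class = "summary_stats")
}

as_summary_stats <- function(x) {
  if (inherits(x, "summary_stats")) return(x)
  if (is.numeric(x) && length(x) == 3L)
    return(summary_stats(x[1], x[2], x[3]))
  if (is.list(x) && all(c("mean", "sd", "n") %in% names(x)))
    return(summary_stats(x$mean, x$sd, x$n))
  stop_domain("cannot interpret object as (mean, sd, n) summary statistics")
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf("<summary_stats> mean = %g, sd = %g, n = %d\n",
              x$mean, x$sd, x$n))
  invisible(x)
}

welch_components <- function(a, b, pooled = FALSE) {
  if (pooled) {
    df <- a$n + b$n - 2
    sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / df
    se <- sqrt(sp2 * (1 / a$n + 1 / b$n))
  } else {
    va <- a$sd^2 / a$n
    vb <- b$sd^2 / b$n
    se <- sqrt(va + vb)
    # Welch-Satterthwaite, kept fractional
    df <- if (se == 0) a$n + b$n - 2
          else (va + vb)^2 / (va^2 / (a$n - 1) + vb^2 / (b$n - 1))
  }
  list(se = se, df = df)
}

#' Two-sample t-test from summary statistics
#'
#' Computes the two-sample t-test directly from two (mean, sd, n) triples,
#' without raw data: `t = (mean_b - mean_a) / sqrt(sd_a^2/n_a +
#' sd_b^2/n_b)` with fractional Welch-Satterthwaite degrees of freedom
#' (default), or the pooled-variance test with `n_a + n_b - 2` df when
#' `pooled = TRUE`.  `alternative = "greater"` tests that group `b`'s mean
#' exceeds group `a`'s.
#'
#' The degenerate case of both sds zero with equal means returns `t = 0`
#' and one-sided `p = 0.5` (two-sided `p = 1`) with a note.
#'
#' @param a,b [summary_stats()] (or numeric `c(mean, sd, n)`).
#' @param alternative `"greater"` (b exceeds a, default), `"less"`, or
#'   `"two.sided"`.
#' @param pooled logical, use the pooled-df test.
#' @return an object of class `"htest"`.
#' @examples
#' welch_t_summary(c(67, 9, 8), c(85, 5, 8))   # one-sided p ~ 2.2e-4
#' @export
welch_t_summary <- function(a, b,
                            alternative = c("greater", "less", "two.sided"),
                            pooled = FALSE) {
  alternative <- match.arg(alternative)
  a <- as_summary_stats(a); b <- as_summary_stats(b)
  if (a$n < 2 || b$n < 2) stop_domain("both groups need n >= 2")
  wc <- welch_components(a, b, pooled = pooled)
  note <- NULL
  if (wc$se == 0) {
    tstat <- 0
    note <- "degenerate: zero standard error (both sds zero)"
  } else tstat <- (b$mean - a$mean) / wc$se
  p <- switch(alternative,
    greater   = stats::pt(tstat, wc$df, lower.tail = FALSE),
    less      = stats::pt(tstat, wc$df),
    two.sided = 2 * stats::pt(abs(tstat), wc$df, lower.tail = FALSE))
  method <- paste0(if (pooled) "Pooled two-sample t-test"
                   else "Welch two-sample t-test",
                   " from summary statistics",
                   if (!is.null(note)) paste0(" (", note, ")"))
  structure(list(
    statistic = c(t = tstat),
    parameter = c(df = wc$df),
    p.value = p,
    estimate = c(`mean difference (b - a)` = b$mean - a$mean),
    stderr = wc$se,
    alternative = alternative,
    method = method,
    data.name = sprintf("a = (%g, %g, %d), b = (%g, %g, %d)",
                        a$mean, a$sd, a$n, b$mean, b$sd, b$n)),
    class = "htest")
}

#' Confidence interval for a mean difference from summary statistics
#'
#' Welch-type interval for `mean_b - mean_a`.  One-sided (default) gives
#' the lower confidence bound with upper bound `+Inf`, as in
#' "11 - Inf" style reporting; `sided = "two"` gives the usual two-sided
#' interval.  No internal rounding: present with `round()` if the
#' nearest-integer convention is wanted.
#'
#' @inheritParams welch_t_summary
#' @param confidence confidence level in (0, 1), default 0.95.
#' @param sided `"one"` (lower bound, upper `+Inf`) or `"two"`.
#' @return a list of class `"interval_estimate"` with `lower`, `upper`,
#'   `confidence`, `sided`, `df`, `estimate`.
#' @examples
#' mean_diff_ci_summary(c(67, 9, 8), c(85, 5, 8))$lower   # ~11.46
#' @export
mean_diff_ci_summary <- function(a, b, confidence = 0.95,
                                 sided = c("one", "two"),
                                 pooled = FALSE) {
  sided <- match.arg(sided)
  if (!is.numeric(confidence) || confidence <= 0 || confidence >= 1)
    stop_domain("confidence must lie strictly in (0, 1)")
  a <- as_summary_stats(a); b <- as_summary_stats(b)
  if (a$n < 2 || b$n < 2) stop_domain("both groups need n >= 2")
  wc <- welch_components(a, b, pooled = pooled)
  diff <- b$mean - a$mean
  if (sided == "one") {
    q <- stats::qt(confidence, wc$df)
    lower <- diff - q * wc$se
    upper <- Inf
  } else {
    q <- stats::qt(1 - (1 - confidence) / 2, wc$df)
    lower <- diff - q * wc$se
    upper <- diff + q * wc$se
  }
  structure(list(lower = lower, upper = upper, confidence = confidence,
                 sided = sided, df = wc$df, estimate = diff),
            class = "interval_estimate")
}

#' @export
print.interval_estimate <- function(x, digits = 4, ...) {
  cat(sprintf("%g%% %s-sided CI for the mean difference: [%s, %s] (df = %s)\n",
              100 * x$confidence, x$sided,
              format(x$lower, digits = digits),
              format(x$upper, digits = digits),
              format(x$df, digits = digits)))
  invisible(x)
}

#' Variance-ratio F-test from summary statistics
#'
#' `F = sd_a^2 / sd_b^2` with `(n_a - 1, n_b - 1)` degrees of freedom.
#' The direction is explicit and groups are never silently reordered:
#' `alternative = "greater"` tests `sigma_a^2 > sigma_b^2`, `"less"` the
#' reverse, `"two.sided"` doubles the smaller tail.
#'
#' @inheritParams welch_t_summary
#' @return an object of class `"htest"`.
#' @examples
#' variance_ratio_test(c(67, 9, 8), c(85, 5, 8))  # F = 3.24, p ~ 0.072
#' @export
variance_ratio_test <- function(a, b,
                                alternative = c("greater", "less",
                                                "two.sided")) {
  alternative <- match.arg(alternative)
  a <- as_summary_stats(a); b <- as_summary_stats(b)
  if (a$n < 2 || b$n < 2) stop_domain("both groups need n >= 2")
  if (a$sd == 0) stop_domain("group a has zero standard deviation")
  if (b$sd == 0) stop_domain("group b has zero standard deviation")
  f <- a$sd^2 / b$sd^2
  df1 <- a$n - 1; df2 <- b$n - 1
  p <- switch(alternative,
    greater   = stats::pf(f, df1, df2, lower.tail = FALSE),
    less      = stats::pf(f, df1, df2),
    two.sided = 2 * min(stats::pf(f, df1, df2),
                        stats::pf(f, df1, df2, lower.tail = FALSE)))
  structure(list(
    statistic = c(F = f),
    parameter = c(`num df` = df1, `denom df` = df2),
    p.value = p,
    alternative = alternative,
    method = "Variance-ratio F-test from summary statistics",
    data.name = sprintf("a = (%g, %g, %d), b = (%g, %g, %d)",
                        a$mean, a$sd, a$n, b$mean, b$sd, b$n)),
    class = "htest")
}
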