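# Affinely rescale a raw sample so it has *exactly* the target mean and
# sd; lets summary-statistics tests be checked against raw-data routines.
rescale_to_summary <- function(x, mean, sd) {
  (x - base::mean(x)) / stats::sd(x) * sd + mean
}

# Printed reference summaries from the ALM cross-section comparison:
# wild type (67, 9, 8) and elongator-mutant (85, 5, 8).
wt_summary <- function() summary_stats(67, 9, 8)
mut_summary <- function() summary_stats(85, 5, 8)

# One-pass Welford mean/variance, an independent oracle for
# summarize_counts' two-pass moments.
welford <- function(x) {
  n <- 0; m <- 0; s <- 0
  for (xi in x) {
    n <- n + 1
    d <- xi - m
    m <- m + d / n
    s <- s + d * (xi - m)
  }
  list(mean = m, var = s / (n - 1), n = n)
}
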