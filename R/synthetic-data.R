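#' Scenario configuration for the count generator
#'
#' Describes one genotype's data-generating process: how many sections,
#' how the per-animal microtubule number `m` is drawn, how stick lengths
#' are drawn, the axon, and the sectioning plan.
#'
#' `m_spec` is one of
#' * `list(kind = "fixed", m = <integer>)`,
#' * `list(kind = "nbinom", mean = <mu>, var = <v>)` — gamma-mixed Poisson
#'   (negative binomial) per-animal `m`, the between-animal overdispersion
#'   mechanism; requires `var > mean`,
#' * `list(kind = "two_point", lower = <integer>, w = <prob>)` — `m` is
#'   `lower + Bernoulli(w)`, the minimum-variance integer distribution
#'   with mean `lower + w` (used to hit non-integer target `m` exactly).
#'
#' `h_spec` is `list(kind = "fixed", h = <um>)` or
#' `list(kind = "uniform", min = , max = )` with support inside `(0, L]`.
#'
#' @param genotype label written into the count table.
#' @param n_sections sections per dataset.
#' @param m_spec,h_spec distribution specifications, see Details.
#' @param L axon length, um.
#' @param convention placement convention, see [axon_geometry()].
#' @param plan_mode `"random"` (one fresh animal per section) or
#'   `"serial"` (serial sections within each animal).
#' @param increment serial increment, um.
#' @param n_animals animals for serial mode (random mode uses one animal
#'   per section).
#' @return an object of class `"scenario_config"`.
#' @export
scenario_config <- function(genotype, n_sections,
                            m_spec, h_spec, L = 100,
                            convention = c("circular", "linear"),
                            plan_mode = c("random", "serial"),
                            increment = 3.2, n_animals = 1L) {
  convention <- match.arg(convention)
  plan_mode <- match.arg(plan_mode)
  axon <- axon_geometry(L, convention)
  m_spec <- validate_m_spec(m_spec)
  h_spec <- validate_h_spec(h_spec, L)
  structure(list(genotype = genotype,
                 n_sections = as.integer(n_sections),
                 m_spec = m_spec, h_spec = h_spec, axon = axon,
                 plan = section_plan(plan_mode, n_sections,
                                     increment = increment),
                 n_animals = as.integer(n_animals)),
            class = "scenario_config")
}

validate_m_spec <- function(s) {
  stopifnot(is.list(s), !is.null(s$kind))
  switch(s$kind,
    fixed = {
      if (!is.numeric(s$m) || s$m < 0 || s$m != as.integer(s$m))
        stop_domain("fixed m must be a non-negative integer")
    },
    nbinom = {
      if (!is.numeric(s$mean) || s$mean <= 0)
        stop_domain("nbinom m mean must be positive")
      if (!is.numeric(s$var) || s$var <= s$mean)
        stop_domain(
          "nbinom (gamma-mixed Poisson) m requires var > mean; got mean = %g, var = %g",
          s$mean, s$var)
    },
    two_point = {
      if (s$lower < 0 || s$lower != as.integer(s$lower) ||
          s$w < 0 || s$w > 1)
        stop_domain("two_point m needs integer lower >= 0 and w in [0, 1]")
    },
    stop_domain("unknown m_spec kind '%s'", s$kind))
  s
}

validate_h_spec <- function(s, L) {
  stopifnot(is.list(s), !is.null(s$kind))
  switch(s$kind,
    fixed = {
      if (!is.numeric(s$h) || s$h <= 0 || s$h > L)
        stop_domain("fixed h must lie in (0, L = %g]", L)
    },
    uniform = {
      if (s$min <= 0 || s$max > L || s$min > s$max)
        stop_domain("uniform h support must lie inside (0, L = %g]", L)
    },
    stop_domain("unknown h_spec kind '%s'", s$kind))
  s
}

draw_m <- function(spec) {
  switch(spec$kind,
    fixed = as.integer(spec$m),
    nbinom = {
      size <- spec$mean^2 / (spec$var - spec$mean)
      stats::rnbinom(1, size = size, mu = spec$mean)
    },
    two_point = as.integer(spec$lower + stats::rbinom(1, 1, spec$w)))
}

draw_h <- function(spec, m) {
  switch(spec$kind,
    fixed = rep(spec$h, m),
    uniform = stats::runif(m, spec$min, spec$max))
}

m_spec_moments <- function(spec) {
  switch(spec$kind,
    fixed = c(mean = as.double(spec$m), var = 0),
    nbinom = c(mean = spec$mean, var = spec$var),
    two_point = c(mean = spec$lower + spec$w, var = spec$w * (1 - spec$w)))
}

#' Analytic moments of a generator scenario
#'
#' Law of total variance for the hierarchical count model with one fresh
#' animal per section: with `p_bar = E(h)/L`,
#' `mean = E(m) p_bar` and
#' `variance = E(m) p_bar (1 - p_bar) + p_bar^2 Var(m)`.
#' (With i.i.d. stick lengths the within-animal Poisson-binomial variance
#' marginalises to the same `p_bar (1 - p_bar)` term, so the formula holds
#' for random as well as fixed stick lengths.)
#'
#' @param config a [scenario_config()].
#' @return a `"moment_pair"` list with `mean` and `variance`.
#' @export
scenario_moments <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  mm <- m_spec_moments(config$m_spec)
  L <- config$axon$length_L
  p_bar <- switch(config$h_spec$kind,
    fixed = config$h_spec$h / L,
    uniform = (config$h_spec$min + config$h_spec$max) / 2 / L)
  structure(list(mean = unname(mm["mean"] * p_bar),
                 variance = unname(mm["mean"] * p_bar * (1 - p_bar) +
                                     p_bar^2 * mm["var"])),
            class = "moment_pair")
}

#' Generate a section-count dataset from a scenario
#'
#' Runs the stick simulator under the scenario's data-generating process.
#' Deterministic per seed: the full generate -> summarise -> test chain
#' reproduces bit-identically for identical `(config, seed)`.
#'
#' @param config a [scenario_config()].
#' @param seed integer seed.
#' @return a `SectionCounts` data frame (`animal_id`, `genotype`,
#'   `section_position_um`, `count`).
#' @export
generate_counts <- function(config, seed = 1L) {
  stopifnot(inherits(config, "scenario_config"))
  mts_rule <- function() {
    m <- draw_m(config$m_spec)
    if (m == 0) return(mt_set(numeric(0)))
    mt_set(draw_h(config$h_spec, m))
  }
  simulate_experiment(mts_rule, config$axon, config$plan,
                      n_animals = config$n_animals,
                      genotype = config$genotype, seed = seed,
                      fresh_animal_per_section =
                        (config$plan$mode == "random"))
}

#' Calibrate a scenario to target count moments
#'
#' Builds an `m_spec` (and fixed `h`) whose population count moments hit
#' `(target_mean, target_var)` exactly under the law of total variance.
#'
#' * Overdispersed target (`target_var > target_mean`): impossible under
#'   any fixed-m independent-stick model (Poisson-binomial bound), so
#'   between-animal variation in `m` is introduced: at crossing
#'   probability `p`, `E(m) = mean/p` and
#'   `Var(m) = (var - mean (1 - p)) / p^2`, realised as a gamma-mixed
#'   Poisson (negative binomial), which requires `Var(m) > E(m)`.
#' * Underdispersed target (`target_var < target_mean`): a fixed-m model
#'   fits, but the implied `m = mean^2 / (mean - var)` is generally not an
#'   integer; `m` is drawn from the two adjacent integers (minimum-
#'   variance mixture) and `p` is re-solved by [stats::uniroot()] so the
#'   total variance still matches exactly.
#'
#' @param target_mean,target_var target population mean and variance of
#'   the section counts.
#' @param L axon length, um.
#' @param p crossing probability `h/L` to use (overdispersed case), or
#'   starting value (underdispersed case, re-solved).  Default 0.7.
#' @param genotype,n_sections passed to [scenario_config()].
#' @return a [scenario_config()] with attribute `"calibration"` recording
#'   the solved parameters.
#' @export
calibrate_scenario <- function(target_mean, target_var, L = 100, p = 0.7,
                               genotype = "sim", n_sections = 8L) {
  stopifnot(target_mean > 0, target_var > 0, p > 0, p < 1)
  if (target_var >= target_mean) {
    mu_m <- target_mean / p
    var_m <- (target_var - target_mean * (1 - p)) / p^2
    if (var_m <= mu_m)
      stop_domain(
        "target is not strictly overdispersed: gamma-mixed m needs Var(m) > E(m) (got %g <= %g)",
        var_m, mu_m)
    m_spec <- list(kind = "nbinom", mean = mu_m, var = var_m)
    cal <- list(p = p, mu_m = mu_m, var_m = var_m,
                mechanism = "between-animal gamma-mixed m")
  } else {
    # total variance at crossing prob q with two-point integer m
    total_var <- function(q) {
      mu_m <- target_mean / q
      w <- mu_m - floor(mu_m)
      target_mean * (1 - q) + q^2 * w * (1 - w) - target_var
    }
    p0 <- 1 - target_var / target_mean   # exact if m were real-valued
    # m-mixture adds variance, so the root lies at q >= p0
    up <- min(p0 + 0.05, 1 - 1e-9)
    q <- if (abs(total_var(p0)) < 1e-12) p0
         else stats::uniroot(total_var, c(p0, up), tol = 1e-12)$root
    mu_m <- target_mean / q
    m_spec <- if (mu_m == floor(mu_m))
      list(kind = "fixed", m = as.integer(mu_m))
    else list(kind = "two_point", lower = as.integer(floor(mu_m)),
              w = mu_m - floor(mu_m))
    p <- q
    cal <- list(p = q, mu_m = mu_m,
                var_m = if (m_spec$kind == "fixed") 0
                        else m_spec$w * (1 - m_spec$w),
                mechanism = "near-fixed m (two-point integer mixture)")
  }
  cfg <- scenario_config(genotype = genotype, n_sections = n_sections,
                         m_spec = m_spec,
                         h_spec = list(kind = "fixed", h = p * L), L = L)
  attr(cfg, "calibration") <- cal
  cfg
}

#' Reference scenario pair: wild-type-like and elongator-mutant-like
#'
#' Two calibrated scenarios whose population count moments equal the
#' reference ALM cross-section summaries: a wild-type-like group with
#' mean 67 and variance 81 (sd 9) — overdispersed, variance above mean,
#' which forces between-animal variation in microtubule number — and an
#' elongator-mutant-like group with mean 85 and variance 25 (sd 5),
#' matching a near-fixed-m model with crossing probability about 0.706
#' (m about 120, h about 0.7 L).  Eight sections per group by default.
#'
#' @param n_sections sections per genotype (default 8).
#' @param L axon length, um (default 100; the reference data fix only
#'   `h/L`, so `L` just sets the length unit).
#' @param p_wt crossing probability used for the wild-type-like
#'   calibration (default 0.7, close to the mutant-side fit).
#' @return a named list of two [scenario_config()]s: `wt` and `elpc1`.
#' @export
alm_scenario_pair <- function(n_sections = 8L, L = 100, p_wt = 0.7) {
  list(
    wt = calibrate_scenario(67, 81, L = L, p = p_wt, genotype = "wt",
                            n_sections = n_sections),
    elpc1 = calibrate_scenario(85, 25, L = L, genotype = "elpc-1(lf)",
                               n_sections = n_sections))
}

#' Generate the reference wild-type-like / mutant-like dataset pair
#'
#' Draws one dataset from each scenario of [alm_scenario_pair()].
#'
#' @param seed integer seed.
#' @inheritParams alm_scenario_pair
#' @return a named list of two `SectionCounts` data frames (`wt`,
#'   `elpc1`), with the scenario configs attached as attribute
#'   `"scenarios"`.
#' @export
alm_reference_pair <- function(seed = 1L, n_sections = 8L, L = 100) {
  sc <- alm_scenario_pair(n_sections = n_sections, L = L)
  out <- list(wt = generate_counts(sc$wt, seed = derive_seed(seed, 1)),
              elpc1 = generate_counts(sc$elpc1,
                                      seed = derive_seed(seed, 2)))
  attr(out, "scenarios") <- sc
  out
}

#' Summarise a count table into per-group (mean, sd, n)
#'
#' Unbiased (n - 1 denominator) sample variance; groups are returned in
#' stable (first-appearance) order.
#'
#' @param counts a `SectionCounts` data frame.
#' @param by grouping column, default `"genotype"`; `NULL` summarises the
#'   whole table as one group.
#' @return a data frame with columns `genotype` (absent when `by` is
#'   `NULL`), `n`, `mean`, `sd`.
#' @export
summarize_counts <- function(counts, by = "genotype") {
  stopifnot(is.data.frame(counts), "count" %in% names(counts))
  one <- function(x, label) {
    if (length(x) < 2)
      stop_domain("group '%s' has fewer than 2 records", label)
    data.frame(n = length(x), mean = mean(x), sd = stats::sd(x))
  }
  if (is.null(by)) return(one(counts$count, "<all>"))
  stopifnot(by %in% names(counts))
  groups <- unique(counts[[by]])
  out <- do.call(rbind, lapply(groups, function(g)
    cbind(stats::setNames(data.frame(g, stringsAsFactors = FALSE), by),
          one(counts$count[counts[[by]] == g], g))))
  rownames(out) <- NULL
  out
}
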