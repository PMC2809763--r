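#' Axon geometry
#'
#' Describes the "tube": an axon of length `L` (micrometres) together with
#' the placement convention for the sticks.  Under the `"circular"`
#' convention stick starts are uniform on `[0, L)` and coverage wraps
#' modulo `L`, so the crossing probability is exactly `h/L` at every
#' section position.  Under the `"linear"` convention sticks must fit
#' inside `[0, L]` (start uniform on `[0, L - h]`), which introduces edge
#' effects near the axon ends; see [crossing_probability()].
#'
#' @param length_L axon length in micrometres, strictly positive.
#' @param convention `"circular"` (default) or `"linear"`.
#' @return an object of class `"axon_geometry"`.
#' @examples
#' axon_geometry(100)
#' @export
axon_geometry <- function(length_L, convention = c("circular", "linear")) {
  convention <- match.arg(convention)
  if (!is.numeric(length_L) || length(length_L) != 1L ||
      !is.finite(length_L) || length_L <= 0)
    stop_domain("`length_L` must be a single positive number, got %s",
                format(length_L))
  structure(list(length_L = as.double(length_L), convention = convention),
            class = "axon_geometry")
}

#' @export
print.axon_geometry <- function(x, ...) {
  cat(sprintf("<axon_geometry> L = %g um, %s convention\n",
              x$length_L, x$convention))
  invisible(x)
}

#' Microtubule set
#'
#' A set of `m` microtubules ("sticks"), each with its own length in
#' micrometres.  The convenience form `mt_set(m = 120, h = 70)` expands a
#' fixed length to all sticks.
#'
#' @param stick_lengths numeric vector of per-microtubule lengths (um),
#'   each strictly positive.  Alternatively leave missing and give `m`,`h`.
#' @param m,h optional fixed-count/fixed-length shortcut.
#' @return an object of class `"mt_set"` with fields `stick_lengths` and
#'   `m`.
#' @examples
#' mt_set(m = 3, h = 10)
#' mt_set(c(5, 7.5, 10))
#' @export
mt_set <- function(stick_lengths = NULL, m = NULL, h = NULL) {
  if (is.null(stick_lengths)) {
    stopifnot(!is.null(m), !is.null(h), m >= 0)
    stick_lengths <- rep(as.double(h), m)
  }
  stick_lengths <- as.double(stick_lengths)
  if (any(!is.finite(stick_lengths)) || any(stick_lengths <= 0))
    stop_domain("all stick lengths must be finite and strictly positive")
  structure(list(stick_lengths = stick_lengths,
                 m = length(stick_lengths)),
            class = "mt_set")
}

#' @export
print.mt_set <- function(x, ...) {
  cat(sprintf("<mt_set> m = %d microtubules, lengths %s um\n", x$m,
              if (x$m == 0) "-" else
                paste0("[", format(min(x$stick_lengths)), ", ",
                       format(max(x$stick_lengths)), "]")))
  invisible(x)
}

check_lengths_fit <- function(mts, axon) {
  if (mts$m > 0 && any(mts$stick_lengths > axon$length_L))
    stop_domain("stick length %g um exceeds axon length L = %g um",
                max(mts$stick_lengths), axon$length_L)
}

#' Probability that one microtubule crosses a section
#'
#' For a stick of length `h` placed uniformly in an axon of length `L`,
#' the probability that it crosses a transverse section.  Circular
#' convention: exactly `h / L`, independent of the section position.
#' Linear convention (start uniform on `[0, L - h]`): an interior section
#' at position `s` with `h <= s <= L - h` is crossed with probability
#' `h / (L - h)`; near the ends the admissible start window is clipped and
#' the probability is `(min(s, L - h) - max(0, s - h)) / (L - h)`.  For
#' `h << L` both conventions reduce to approximately `h / L`.
#'
#' @param h stick length, um, in `(0, L]`.
#' @param axon an [axon_geometry()].
#' @param position section position in `[0, L)`.  Ignored under the
#'   circular convention; under the linear convention `NULL` returns the
#'   interior value `h / (L - h)`.
#' @return a probability in `[0, 1]`.
#' @examples
#' crossing_probability(5, axon_geometry(10))          # 0.5
#' crossing_probability(10, axon_geometry(110, "linear")) # 0.1 interior
#' @export
crossing_probability <- function(h, axon, position = NULL) {
  stopifnot(inherits(axon, "axon_geometry"))
  L <- axon$length_L
  if (!is.numeric(h) || any(!is.finite(h)) || any(h <= 0) || any(h > L))
    stop_domain("stick length h = %s must lie in (0, L = %g]",
                paste(format(h), collapse = ", "), L)
  if (!is.null(position) && any(position < 0 | position >= L))
    stop_domain("section position must lie in [0, L = %g)", L)
  if (axon$convention == "circular") return(h / L)
  # linear: degenerate full-length stick crosses every interior section
  out <- ifelse(h == L, 1, h / (L - h))
  if (is.null(position)) return(pmin(out, 1))
  win <- pmin(position, L - h) - pmax(0, position - h)
  ifelse(h == L, 1, pmin(pmax(win, 0) / (L - h), 1))
}

#' Place microtubules uniformly along the axon
#'
#' Draws one start coordinate per stick: i.i.d. uniform on `[0, L)` under
#' the circular convention, uniform on `[0, L - h]` per stick under the
#' linear convention (a full-length stick, `h = L`, is forced to start at
#' 0).  Reproducible: identical `(mts, axon, seed)` give bit-identical
#' starts; the caller's RNG state is left untouched.
#'
#' @param mts an [mt_set()].
#' @param axon an [axon_geometry()].
#' @param seed integer seed.
#' @return an object of class `"stick_placement"` with fields `starts`,
#'   `mts`, `axon`, `rng_seed`.
#' @export
place_sticks <- function(mts, axon, seed) {
  stopifnot(inherits(mts, "mt_set"), inherits(axon, "axon_geometry"))
  check_lengths_fit(mts, axon)
  L <- axon$length_L
  starts <- with_seed(seed, {
    if (mts$m == 0) numeric(0)
    else if (axon$convention == "circular") stats::runif(mts$m, 0, L)
    else stats::runif(mts$m, 0, L - mts$stick_lengths)  # h = L -> start 0
  })
  structure(list(starts = starts, mts = mts, axon = axon,
                 rng_seed = seed),
            class = "stick_placement")
}

#' Count microtubule intersections at transverse sections
#'
#' The count at section position `s` is the number of sticks whose
#' coverage interval `[a, a + h)` — taken modulo `L` under the circular
#' convention — contains `s`.  Intervals are half-open so boundary hits
#' are unambiguous and results are bit-exact.
#'
#' @param placement a [place_sticks()] result.
#' @param positions numeric vector of section positions, each in `[0, L)`.
#' @return integer vector of counts, one per position, each in `[0, m]`.
#' @examples
#' ax <- axon_geometry(10)
#' pl <- place_sticks(mt_set(5), ax, seed = 1)
#' count_intersections(pl, c(1, 7))
#' @export
count_intersections <- function(placement, positions) {
  stopifnot(inherits(placement, "stick_placement"))
  L <- placement$axon$length_L
  if (any(positions < 0 | positions >= L))
    stop_domain("section position %s outside [0, L = %g)",
                format(positions[positions < 0 | positions >= L][1]), L)
  starts <- placement$starts
  h <- placement$mts$stick_lengths
  if (length(starts) == 0L) return(integer(length(positions)))
  if (placement$axon$convention == "circular") {
    vapply(positions, function(s)
      sum(((s - starts) %% L) < h), integer(1))
  } else {
    vapply(positions, function(s)
      sum(starts <= s & s < starts + h), integer(1))
  }
}

#' Section plan
#'
#' Where the transverse sections are taken.  `"random"` mode draws
#' `n_sections` positions independently and uniformly on `[0, L)` —
#' emulating random sections across different animals.  `"serial"` mode
#' takes an arithmetic sequence of `n_sections` positions spaced
#' `increment` um apart (default 3.2 um, the serial-sectioning increment
#' used for single-animal series), starting at `first`; `first = NULL`
#' draws a seeded uniform offset in `[0, increment)` at simulation time.
#'
#' @param mode `"random"` or `"serial"`.
#' @param n_sections positive integer number of sections.
#' @param increment serial spacing in um (serial mode only).
#' @param first first serial position in um, or `NULL` for a seeded
#'   uniform offset.
#' @return an object of class `"section_plan"`.
#' @export
section_plan <- function(mode = c("random", "serial"), n_sections,
                         increment = 3.2, first = NULL) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(n_sections), n_sections >= 1,
            n_sections == as.integer(n_sections))
  if (mode == "serial" && (!is.numeric(increment) || increment <= 0))
    stop_domain("serial increment must be positive, got %s",
                format(increment))
  structure(list(mode = mode, n_sections = as.integer(n_sections),
                 increment = as.double(increment), first = first),
            class = "section_plan")
}

# resolve a plan to concrete positions (RNG caller-managed)
plan_positions <- function(plan, L) {
  if (plan$mode == "random") return(stats::runif(plan$n_sections, 0, L))
  first <- if (is.null(plan$first)) stats::runif(1, 0, plan$increment)
           else plan$first
  pos <- first + plan$increment * (seq_len(plan$n_sections) - 1L)
  if (any(pos < 0 | pos >= L))
    stop_domain(
      "serial plan leaves [0, L): first = %g, increment = %g, n = %d, L = %g",
      first, plan$increment, plan$n_sections, L)
  pos
}

#' Simulate a sectioning experiment
#'
#' Composes [place_sticks()] and [count_intersections()] into a labelled
#' count table.  With a `"random"` plan and `fresh_animal_per_section =
#' TRUE` (the default for random plans) every section comes from a newly
#' simulated animal, so counts are independent across records — the
#' random-sections-across-animals design.  With a `"serial"` plan each of
#' `n_animals` animals is placed once and sectioned at all plan positions,
#' so counts within an animal share the same sticks and are dependent —
#' the single-animal serial-sectioning design.
#'
#' Each animal runs in its own RNG substream derived from `seed` via
#' [derive_seed()], so enlarging the experiment never reshuffles earlier
#' animals.
#'
#' @param mts an [mt_set()] shared by all animals, or a function
#'   `function()` returning a fresh `mt_set` per animal (called inside the
#'   animal's RNG substream, e.g. to draw a random microtubule number).
#' @param axon an [axon_geometry()].
#' @param plan a [section_plan()].
#' @param n_animals number of animals (ignored when
#'   `fresh_animal_per_section` is `TRUE`: one animal per section).
#' @param genotype label stored in the output.
#' @param seed integer top-level seed.
#' @param fresh_animal_per_section logical; default `TRUE` for random
#'   plans, `FALSE` for serial plans.
#' @return a `SectionCounts` data frame with columns `animal_id`,
#'   `genotype`, `section_position_um`, `count`.
#' @examples
#' simulate_experiment(mt_set(m = 120, h = 70), axon_geometry(100),
#'                     section_plan("random", 8), genotype = "wt", seed = 1)
#' @export
simulate_experiment <- function(mts, axon, plan, n_animals = 1L,
                                genotype = "sim", seed = 1L,
                                fresh_animal_per_section =
                                  (plan$mode == "random")) {
  stopifnot(inherits(axon, "axon_geometry"), inherits(plan, "section_plan"),
            n_animals >= 1)
  make_mts <- if (is.function(mts)) mts else function() mts
  one_animal <- function(i, positions_n) {
    aseed <- derive_seed(seed, i)
    with_seed(aseed, {
      a_mts <- make_mts()
      check_lengths_fit(a_mts, axon)
      starts <- if (a_mts$m == 0) numeric(0)
        else if (axon$convention == "circular")
          stats::runif(a_mts$m, 0, axon$length_L)
        else stats::runif(a_mts$m, 0, axon$length_L - a_mts$stick_lengths)
      pl <- structure(list(starts = starts, mts = a_mts, axon = axon,
                           rng_seed = aseed), class = "stick_placement")
      pos <- if (is.null(positions_n)) plan_positions(plan, axon$length_L)
             else stats::runif(positions_n, 0, axon$length_L)
      data.frame(animal_id = sprintf("animal_%04d", i),
                 genotype = genotype,
                 section_position_um = pos,
                 count = count_intersections(pl, pos),
                 stringsAsFactors = FALSE)
    })
  }
  recs <- if (fresh_animal_per_section) {
    if (plan$mode != "random")
      stop_domain("fresh_animal_per_section requires a random plan")
    lapply(seq_len(plan$n_sections), one_animal, positions_n = 1L)
  } else {
    lapply(seq_len(n_animals), one_animal, positions_n = NULL)
  }
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}
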