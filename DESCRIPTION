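Package: mtsticks
Title: Stick Models and Moment Inference for Axonal Microtubule
    Cross-Section Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Stochastic "sticks-in-a-tube" model of microtubule
    cross-section counts in an axon: microtubules are axis-parallel
    segments of length h placed uniformly along an axon of length L, and
    the observable is the number of segments crossing a transverse
    section.  Provides the generative simulator (random sections across
    animals and serial sections within one animal), analytic binomial
    count moments, method-of-moments inversion that estimates microtubule
    number and length from a count table, summary-statistics two-sample
    inference (Welch t, one-sided confidence bound, variance-ratio F),
    a decision rule discriminating "more microtubules" from "longer
    microtubules", overdispersed hierarchical count generators for
    between-animal variability, and Monte-Carlo power analysis of the
    whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: stats
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
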