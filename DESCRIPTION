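Package: switchsim
Title: Individual-Based Simulation of Mating-Type Switching Evolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Individual-based simulations of finite haploid populations with
    alternating clonal and sexual phases, for studying the evolution of
    stochastic mating-type switching. Cells carry a mating-type locus with m
    alleles and a switching locus that sets the per-division probability that
    one daughter cell changes mating type. The package implements the full
    life cycle (clonal growth rounds with switching and cost-weighted
    survival, random heterotypic pair formation under exhaustive or speedy
    mating, meiosis and regrowth to carrying capacity) together with
    replicate-level experiment harnesses: fixation-probability estimation for
    switching alleles, mating-type distortion and extinction trajectories,
    cost-benefit invasion grids, proportion-mated summaries, and
    continuum-of-alleles evolution of the switching rate under
    mutation-selection balance. Results are written as tab-separated tables
    with JSON run manifests, and every harness is exposed through a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
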