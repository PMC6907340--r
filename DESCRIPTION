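Package: beebreedsim
Title: Stochastic Simulation of Honeybee Breeding Schemes with and without
    Controlled Mating
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates honeybee breeding populations under truncation
    selection on a maternally and directly affected quantitative trait.
    Implements a bivariate (maternal, direct) infinitesimal genetic model and
    a finite-locus alternative that both respect the haplodiploid inheritance
    of honeybees, haplodiploid pedigree bookkeeping with exact inbreeding
    coefficients, a bee-specific sparse inverse relationship matrix with
    mating stations acting as pseudo-sires, yearly best linear unbiased
    prediction (BLUP) of maternal and direct effects, and the coupling of the
    selected breeding population to an unselected passive population.
    Provides replicate management, summary statistics (genetic gain, gain
    decomposition, genetic lag, long-term variance erosion) and CSV/JSON
    reporting for simulation experiments over grids of population parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    methods,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
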