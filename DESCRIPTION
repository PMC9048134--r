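Package: flimfret
Title: Stoichiometry of Membrane-Protein Complexes from FLIM/FRET Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for inferring the composition of membrane-protein
    regulatory complexes from live-cell fluorescence lifetime (FLIM/TCSPC)
    and FRET measurements. Implements Poisson maximum-likelihood
    decomposition of photon-arrival histograms into exponential decay
    species (including global analysis with shared lifetimes),
    FRET efficiency/distance/concentration conversions, hyperbolic
    FRET binding-curve fitting for apparent dissociation constants,
    a binomial forward model and classifier for progressive
    acceptor-photobleaching donor/acceptor curvature, a mass-action
    model of concentration-dependent complex assembly, and rule-based
    elimination among candidate complex stoichiometries. A seeded
    synthetic-data generator emulates every input so the whole pipeline
    is testable without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
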