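Package: stembreakr
Title: Size-Standardised Analysis of Storm-Induced Tree Stem Breakage
Version: 0.1.0
Authors@R:
    person("Forest", "Dynamics Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing tree stem breakage after extreme ice or
    snow storms. Fits a unimodal Power Ricker curve for size-dependent
    breakage probability by adaptive Markov chain Monte Carlo, partitions
    the variance of size-standardised breakage across crossed taxon
    (family, species-in-family) and stand random effects, quantifies the
    relative importance of stand and trait fixed effects, tests for
    phylogenetic signal in species-level susceptibility (Blomberg's K,
    Pagel's lambda), and recomputes community-weighted trait means and
    functional dispersion after a damage-specific basal-area adjustment.
    A synthetic forest-inventory generator with the same statistical
    structure makes every stage testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    lme4,
    optparse,
    stats,
    utils,
    tools
Suggests:
    cluster,
    MASS,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
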