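Package: selsym
Title: Symmetry Analysis and State-Space Reduction for Models of Natural Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for finite two-allele models of natural selection viewed
    from the gene's-eye perspective: a population is a fixed set of genetic
    sites, and each time step samples a parentage map (which site each allele
    is copied from) and a mutation set (which sites flip allele) from a
    state-dependent distribution. The package builds the exact Markov chain on
    binary population states, decides the fixation axiom with a verifiable
    witness, detects the symmetry group of a process (permutations of sites
    that preserve replacement and mutation probabilities), reduces the chain
    to orbits of the group action, and counts or bounds the number of reduced
    states by Burnside/Polya enumeration. Built-in constructors cover the
    standard model families: well-mixed Moran and Wright-Fisher, graph-based
    Moran updating (cycles, stars, arbitrary weighted graphs), class-structured
    and island-structured populations, plus explicit user-supplied tables with
    exact rational probabilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    igraph,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
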