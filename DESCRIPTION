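Package: icefloe
Title: Population Genetics of Holarctic Bowhead Whales from Ancient and
    Modern Mitochondrial DNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing aligned mitochondrial D-loop sequence data
    from heterochronous (ancient and modern) sample sets of bowhead whales
    and other matrilineally structured species. Computes per-population
    diversity statistics (haplotype diversity, nucleotide diversity,
    Watterson's theta), AMOVA-based Phi_ST and frequency F_ST with
    permutation tests and false-discovery-rate correction, optimal minimum
    spanning haplotype networks, and microsatellite probability-of-identity
    duplicate screens. Includes a serial (heterochronous) coalescent
    simulator over multiple demes with migration, size changes and
    divergence events, HKY+Gamma sequence mutation, a 36-scenario
    demographic design bank encoding whaling-bottleneck priors, and a
    highest-posterior-density scenario-rejection engine that compares
    observed pairwise Phi_ST values against simulated distributions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    igraph,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
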