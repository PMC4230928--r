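Package: tigerscape
Title: Landscape Genetics and Habitat Connectivity for Fragmented Carnivore Populations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: An end-to-end toolkit for landscape-genetic inference from
    non-invasive microsatellite surveys of territorial carnivores in
    fragmented habitat.  Covers consensus genotyping and individual
    identification from replicated scat genotypes (probability-of-identity
    statistics), population differentiation (Weir-Cockerham F-ST, allele-size
    R-ST, hierarchical AMOVA with Phi statistics, PCoA), Bayesian admixture
    clustering with the Evanno delta-K criterion, likelihood and Bayesian
    detection of first- and second-generation migrants with a consensus
    designation rule, genetic bottleneck diagnostics (M-ratio,
    heterozygosity-excess, mode-shift), single-season occupancy models with
    imperfect detection and AIC model averaging, occupancy-derived cost
    surfaces with least-cost corridors and circuit-theory resistance
    distances, and Mantel / partial-Mantel validation of corridor models
    against linearized genetic distances.  A seeded forward-time simulator of
    landscapes, metapopulations, noisy scat genotypes and detection surveys
    supports power analysis and parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    Matrix,
    igraph
Suggests:
    testthat (>= 3.0.0),
    vegan,
    MASS,
    jsonlite
Config/testthat/edition: 3
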