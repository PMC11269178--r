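Package: paleoclock
Title: Generation-Time Clocks and Reproductive-Control Proxies for
    Time-Stamped Ancient Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Molecular proxies of reproductive control in serially
    sampled (time-stamped) genome panels, built around pseudo-haploid
    transversion genotypes. Implements a mutation clock (per-genome
    derived-mutation density converted to generations since the
    ancestral sequence), a recombination clock (decay, with genetic
    distance, of the probability that two sites are jointly derived in
    one genome, fitted by least squares to recover per-sample
    generations since the most recent common ancestor), runs of
    homozygosity from windowed pseudo-heterozygosity with close-kin
    mating detection, penalized-spline trend detection for temporal
    shifts in generation time, and calendar arithmetic between
    generation counts and years BCE. A serial-coalescent synthetic-data
    generator (driven by msprime through a bundled Python helper)
    reproduces the validation design of the method so that every stage
    is testable without ancient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    mgcv,
    Rcpp,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    GenomicRanges,
    SummarizedExperiment,
    S4Vectors
SystemRequirements: Python (>= 3.8) with msprime and numpy, required
    only by the synthetic-data generator (simulate_cohort).
Config/testthat/edition: 3
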