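Package: dronemap
Title: Recombination and De Novo Mutation Rates from Haploid Drone Colonies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates the meiotic crossover landscape and the de novo
    mutation rate of a social-insect queen from whole-genome haploid
    genotypes of her drone offspring. Implements marker screening for
    haploid cohorts, queen-haplotype phasing by adjacent-marker majority
    linkage, crossover/noncrossover classification with shared double
    crossover artifact removal, strict drone-unique mutation calling with
    callable-site accounting and exact Poisson confidence intervals, and
    the accompanying randomization statistics (Monte-Carlo dispersion,
    mutation-breakpoint proximity, GC-biased conversion direction,
    between-species rate permutation). A seeded colony simulator generates
    queens, recombinant gametes, mutations and noisy genotype observations
    with ground truth, so every stage is verifiable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    Biostrings,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
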