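Package: sealmix
Title: Population Structure and Seasonal Movement Analysis for Ringed Seals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Population-genetic and satellite-telemetry analyses for
    multi-site pinniped studies: GenePop genotype and aligned-FASTA
    ingestion, Tamura-Nei gamma-corrected sequence distances and
    multiset genotype distances, within-site diversity statistics
    (heterozygosity, Monte-Carlo Hardy-Weinberg and linkage tests,
    rarefied allelic richness, duplicate-genotype screening),
    between-site differentiation (Weir-Cockerham F_ST, distance-matrix
    AMOVA, average pairwise differences), the Hudson-Boos-Kaplan K_ST
    permutation test of panmixia, and seasonal movement and haulout
    summaries for Argos-tracked seals. Includes synthetic-data
    generators (island-model genotypes, haplotype pools, movement
    tracks) that emulate the sampling structure of a multi-subspecies
    ringed-seal study so every stage is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Biostrings,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ape,
    geosphere,
    jsonlite,
    optparse
Config/testthat/edition: 3
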