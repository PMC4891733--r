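Package: droneselect
Title: Selection Scans, CNV Screening and Mitotype Reconstruction for Haploid Drone Resequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Population-genomic analyses tailored to whole-genome resequencing of
    haploid honeybee drones. Implements the FLK and hapFLK selection-signature
    statistics with a fastPHASE-style haplotype-cluster model, empirical
    chi-squared p-value calibration, significance-region calling and spectral
    decomposition of the population kinship matrix to assign the population
    under selection; detection of clustered heterozygous calls in haploids as
    candidate copy-number variants with population-bias tests; reconstruction
    of the mitochondrial tRNA-Leu/cox2 mitotype from sequencing reads scored
    against a reference panel; windowed nucleotide diversity, Reynolds
    distances, kinship construction from a rooted population tree, and a
    depth-versus-callable-fraction calibration curve. A seeded synthetic-data
    generator emulating hierarchical drift, selective sweeps, collapsed
    duplications and mitotype architecture makes the whole pipeline testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    GenomicRanges,
    IRanges,
    jsonlite,
    Rcpp,
    rtracklayer,
    stats,
    tools,
    utils,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
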