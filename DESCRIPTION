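Package: fecundscan
Title: Selection-Signature Scan for Fecundity Candidate Genes from SNP-Array Genotypes
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-signature genome scan for detecting candidate genes associated
    with fecundity in small phenotype-divergent livestock populations, as used
    for Katahdin ewes genotyped on a ~50k SNP array. Implements phenotype
    adjustment by a Gaussian linear model with Wald screening of covariates,
    hierarchical clustering of adjusted phenotypes into high/low fecundity
    subpopulations, marker quality control (minor allele frequency,
    Hardy-Weinberg exact test, call rate), principal components of the
    genotype matrix, sliding-window detection of runs of homozygosity with
    consensus candidate haplotypes, per-SNP within-group fixation indices and
    Weir-Cockerham F_ST with quantile-based candidate selection, and +/-50 kb
    candidate-region annotation against a gene map. Includes a synthetic
    PED/MAP genotype and phenotype generator with planted autozygosity and
    allele-frequency-differentiated loci plus ground-truth tables, so the full
    pipeline is testable without proprietary genotypes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    ape,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
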