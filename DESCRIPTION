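Package: mutload
Title: Deleterious Mutation Load, Complementation, and Genetic Architecture
    in Crop Breeding Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Severity-stratified accounting of deleterious mutation load across
    breeding eras, hybrid complementation statistics, heterosis metrics, site
    frequency spectrum projection and joint spectra between heterotic groups,
    GBLUP additive-dominance variance components with SNP-effect backsolution,
    a BayesS-style sampler for the coupling between SNP effect size and allele
    frequency, interval-based enrichment of deleterious variants, inbreeding
    coefficients and runs of homozygosity, and a forward Wright-Fisher
    generator of synthetic breeding panels that makes the whole pipeline
    testable without resequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    rtracklayer,
    vcfR,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
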