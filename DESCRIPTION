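Package: polycap
Title: Target-Capture Variant, Dosage, CNV and Divergence Analysis for
    Polyploids
Version: 0.1.0
Authors@R:
    person("Polycap", "Developers", email = "polycap-dev@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for hybridization target-capture sequencing
    of high-ploidy plant genomes such as the Saccharum (sugarcane)
    complex.  Implements a multi-caller variant hard-filter cascade with
    caller concordance summaries, binomial/multinomial allele-dosage
    genotyping with single-dose-marker identification at ploidies 6-12,
    normalized read-depth gene CNV and presence/absence detection,
    gene-model based functional annotation of SNPs and InDels,
    thermodynamic feature computation and linear capture-efficiency
    modelling for 120-mer probes, Nei-Gojobori style Ka/Ks estimation
    with molecular dating, and neighbor-joining SNP trees with bootstrap
    support.  A synthetic-data module generates every input with known
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    data.table,
    jsonlite,
    ape,
    Rcpp,
    Biostrings,
    IRanges
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
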