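Package: atoxfam
Title: Screening, Alignment, Phylogenetics and Signature Mining for the
    Allatotropin/Orexin GPCR Family
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, fully testable analysis of Allatotropin/Orexin
    (AT/Ox) G-protein coupled receptor families: Kyte-Doolittle hydropathy
    screening for the seven transmembrane helices, detection of the anchored
    E/DRWYAI family motif at the TMIII/IC-loop-2 interface, progressive
    multiple sequence alignment with affine gaps, Poisson-corrected distance
    phylogenetics with Neighbour-Joining, bootstrap and majority-rule
    consensus, a Felsenstein pruning likelihood scorer under an equal-rates
    amino-acid model, clade-specific signature-motif mining, and a
    ground-truthed sequence simulator that evolves GPCR-like families along a
    known tree so every pipeline stage can be validated against planted truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr
LinkingTo:
    Rcpp
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
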