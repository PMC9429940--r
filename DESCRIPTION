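Package: nitramp
Title: Processing-Method Sensitivity Analysis for Functional-Gene Amplicons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify how amplicon processing choices change the
    ecological conclusions drawn from protein-coding functional-gene surveys
    (nitrogen-cycle genes such as amoA, nxrB, nirS, nirK and nrfA). The
    package pairs a seeded synthetic amplicon-community generator with two
    feature-reconstruction routes (greedy identity-threshold OTU clustering
    and an abundance-skew exact-variant denoiser), a protein-translation
    quality-check framework (frame detection, stop-codon screening, length
    gating and alignment-based enzyme verification), alpha/beta diversity
    with rarefaction and UniFrac, Mantel and PERMANOVA permutation tests,
    Hellinger + canonical correspondence analysis with stepwise driver
    selection, an incremental Robinson-Foulds tree-congruence procedure, and
    naive Bayesian and lowest-common-ancestor taxonomy classifiers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan
Suggests:
    phangorn,
    phyloseq,
    seqinr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
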