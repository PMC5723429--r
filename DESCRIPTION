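Package: cocoamap
Title: SNP Array Panel Design, F1 Outcross Segregation Analytics and QTL
    Scanning for Cacao
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for building and exploiting a mid-density Infinium SNP
    genotyping array in an outbreeding tree crop. Covers candidate-variant
    filtering and bead-type budgeting for panel design, genotype-matrix
    quality control with GenTrain/GenCall score filters, full-sib (CP)
    family segregation typing, chi-square inference of an unknown parent
    from progeny segregation, Mendelian-error off-type screening,
    cross-platform genotype concordance tables, derived yield and
    disease-resistance phenotypes, and a single-marker interval-style QTL
    scan with composite-interval cofactors and a Li-Ji effective-test
    corrected significance threshold. A seeded synthetic F1-cross
    generator (Haldane recombination, genotyping error, off-type
    injection, planted QTL) exercises every stage end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
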