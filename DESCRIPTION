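Package: conet
Title: Cox Proportional-Hazards Network Regression for Survival
    Outcomes in TWAS
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Network regression for survival outcomes in two-stage
    transcriptome-wide association studies (TWAS). Genetically predicted
    gene expressions form the nodes of a prior-known gene network; each
    network edge is quantified per individual by pointwise mutual
    information (PMI) estimated with bivariate kernel density estimation.
    Node and edge effects on a survival phenotype are then tested jointly
    in a Cox proportional-hazards model with Wald tests and
    Benjamini-Hochberg false-discovery-rate adjustment. Includes a
    product-moment edge comparator, eQTL-weight based expression
    prediction with a ridge trainer, and a Weibull survival simulation
    engine for type-I-error and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    survival,
    KernSmooth,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    vcfR,
    withr
Config/testthat/edition: 3
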