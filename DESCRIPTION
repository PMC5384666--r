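Package: varfact
Title: Genotype-Phenotype Cohort Queries over an Observation-Fact Warehouse
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates annotated sequence variants and clinical phenotypes in
    a star-schema observation-fact warehouse with i2b2-style modifier and
    instance-number semantics. Provides an ETL from multi-sample VCF plus
    per-variant annotation tables through a GVF-like intermediate into
    Sequence Ontology coded fact n-tuples, a panel-based cohort query engine
    (OR within panels, AND across panels, exclusions, same-instance groups),
    a JSON document store with precomputed field views and progressive
    patient-set filter chains, subset comparison statistics (chi-square,
    Welch t), and a synthetic multi-population cohort generator with a
    brute-force ground-truth oracle for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    stringr,
    readr,
    jsonlite,
    yaml,
    vcfR,
    ggplot2,
    generics,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
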