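Package: bdokit
Title: Knowledge Modelling and Decision Support for the Skeletal Dysplasia Nosology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building, validating and analysing an ontology of the
    skeletal dysplasia nosology. Provides a typed knowledge base (disease groups
    and dysplasias, genes, gene mutations, proteins, and entity-quality phenotype
    composites) organised as a subclass DAG, a restricted Manchester-style class
    expression grammar with a closed-world structural validator, an HGVS-derived
    gene-mutation encoding parser, MIREOT-style external term references, and
    decision-support analytics: phenotype profile overlap, Jaccard disorder
    ranking, Apriori association-rule mining refined by class axioms, and
    dictionary annotation of clinical text. A seeded synthetic nosology and
    patient-cohort generator reproduces the structural statistics of the real
    ontology so every component is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
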