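Package: phenosev
Title: Severity Annotation and Scoring of Phenotype Ontology Terms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotates phenotype ontology terms (such as the Human Phenotype
    Ontology) with the frequency at which each phenotype directly causes ten
    severity-related clinical characteristics, using a pluggable annotator
    contract (a user-supplied large language model adapter, or the bundled
    deterministic, random and planted-truth annotators). The
    annotations are converted into a weighted composite severity score on a
    0-100 scale and a four-level severity class via a tier-based decision
    tree. Includes ontology loading (OBO and obographs JSON), truth-set
    construction from ontology branches, replicate-consistency and recall
    benchmarking, indirect-causation auditing, synthetic fixture generators,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
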