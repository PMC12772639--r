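Package: clinkg
Title: Clinical Knowledge Graphs with Two-Phase Incremental Updates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Build and maintain a clinical knowledge graph from guideline-style
    documents and structured EMR records. Provides a property-graph store with
    atomic, idempotent merge semantics and attribute indices; a terminology
    service with code crosswalks (ICD-10-CM, SNOMED CT, RxNorm, LOINC) and a
    three-stage term-normalization cascade; phase-1 information extraction
    (dictionary recognition, surface-pattern relations, EMR schema alignment,
    temporal precedence, comorbidity attribution); phase-2 validated,
    conflict-checked, temporally tagged graph updates with authority-based
    supersedence and change accounting; entity, path and subgraph queries with
    provenance; a seeded synthetic-corpus generator with a ground-truth
    manifest; and evaluation utilities (BLEU, ROUGE-L, rating aggregation,
    LLM-call accounting).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
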