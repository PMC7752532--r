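Package: oncolex
Title: Consumer-Term Cancer Ontology and Social Media Post Frequency Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for ontology-driven analysis of cancer-related social
    media posts written in consumer language. Provides a consumer-term
    cancer ontology model (a nine-superclass concept hierarchy with a
    synonym terminology) with loading, validation and traversal; corpus
    ingestion with pattern-based de-identification and date filtering;
    dictionary concept annotation with stop-phrase masking and
    advertising-post removal; post-level frequency analysis with superclass
    rollup, cancer-type stratification, ranking and registry comparison;
    and a synthetic corpus generator with planted ground truth so every
    stage is testable without access to the original crawled data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    rlang,
    stringi,
    tibble,
    tidyr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
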