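Package: phido
Title: Ontology-Driven Dialogue Management for Patient Health Counseling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds an OWL2 application ontology for patient health
    information dialogue (classes for discussions, communication goals,
    speech tasks and Searle-annotated utterances), compiles declarative
    counseling scripts into instance-level session graphs, executes a
    focus-tracking finite-state dialogue engine over those graphs, and
    scores ontologies with a semiotic quality metric suite (lawfulness,
    richness, interpretability, consistency, clarity, comprehensiveness
    and their syntactic, semantic and pragmatic composites). A persona
    simulator generates synthetic counseling scripts and participant
    behaviour so every dialogue path can be exercised without human input.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    xml2,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
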