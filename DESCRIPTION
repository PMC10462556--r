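Package: llrsim
Title: Surgical Process Modelling and Discrete-Event Simulation of
    Laparoscopic Liver Resection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing surgical step logs of parenchyma-sparing
    laparoscopic liver resection (LLR) and for simulating whole procedures
    with a discrete-event simulation model. The package represents the
    surgical process model (phases, modules, decision points) for three
    tumour-location categories, reads and verifies timed step logs,
    computes per-module duration and occurrence statistics, extracts
    most-probable workflow paths, generates synthetic cohorts with the
    statistical structure of published summary tables, and predicts the
    impact of an intra-operative navigation platform under three
    technology scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
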