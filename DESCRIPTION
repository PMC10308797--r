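Package: ddpsim
Title: Simulation of Drug Development Process Segments in Oncology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stylized Monte-Carlo models of oncology drug development process
    (DDP) segments: pairs of consecutive clinical trials with a go/no-go gate
    between them. Implements three segment types -- a single-arm phase II
    trial (one-sided exact binomial test) followed by an adaptively sized
    phase III randomized controlled trial (one-sided Fisher exact test), a
    phase I Continual Reassessment Method dose-finding trial followed by a
    single-arm phase II trial with a toxicity monitor, and a phase II adaptive
    biomarker-enrichment randomized trial (paired exact McNemar analysis)
    followed by a phase III trial in the selected subpopulation. Provides
    exact power computations, data-driven sample-size selection with caps,
    truth-scenario generators, a seeded replication engine, operating
    characteristic metrics with Monte-Carlo standard errors, parameter
    sweeps, and a YAML configuration interface with CSV/JSON reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
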