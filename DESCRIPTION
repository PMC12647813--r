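Package: narrec
Title: Semantic Narrative Networks and Multi-Session Naturalistic Recall Analysis
Version: 0.1.0
Authors@R:
    person("Narrec", "Maintainers", email = "maintainers@narrec.org", role = c("aut", "cre"))
Description: Tools for analysing naturalistic episodic memory experiments in
    which participants watch short videos and verbally recall them across
    several sessions. Annotated video events are embedded as sentence vectors
    and turned into per-video semantic narrative networks; an event's semantic
    centrality (normalized weighted degree, z-scored within video) is used to
    predict recall success and detail production with logistic and Poisson
    mixed models (participant and video random intercepts, Type III Wald
    tests, simple slopes, simulation-based power). Also included: event
    boundary agreement between raters (precision/recall/F1 with temporal
    tolerance), intraclass correlation for detail scoring, Jaccard lexical
    overlap of recall transcripts within and between participants, and a fully
    seeded synthetic-study generator with known ground truth for calibration
    and recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    lme4,
    stats,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
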