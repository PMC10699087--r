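Package: boolkit
Title: Reaction-Contingency Knowledge Bases and Bipartite Boolean
    Simulation of NLRP3 Inflammasome Signalling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for encoding signal-transduction networks as
    reaction-contingency knowledge bases (site-specific elemental states,
    typed elemental reactions, and required/inhibitory/neutral
    contingencies with nested Boolean gates), compiling them into
    bipartite Boolean models, and simulating them synchronously.
    Includes natural off-state discovery, attractor detection, scenario
    execution with clamped inputs, regulatory-graph export, a random
    network generator with an independent reference interpreter for
    property testing, and a curated model of NLRP3 inflammasome priming,
    licensing, triggering and turnover together with a catalogue of
    in-silico stimulus, inhibitor and mutation experiments.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
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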