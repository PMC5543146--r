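Package: wheatnet
Title: Dynamic Preferential-Attachment Modelling of the Global Wheat Trade Network
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the growth of the directed, unweighted global wheat
    trade network by fitness-based preferential attachment with an
    exponentially decaying Maslov-Sneppen rewiring step. Provides the
    continuous (multi-year sustained) trade-network extraction from annual
    bilateral trade tables, a suite of directed-network structure and
    resilience metrics, grid-sweep calibration of the growth parameters by
    replicate-averaged normalized mean squared error, and a shock engine for
    simulating export-ban errors and targeted attacks of configurable
    severity, duration, targeting and repetition during network formation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
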