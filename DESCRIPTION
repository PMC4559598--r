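Package: dynconn
Title: Dynamic Functional Brain Network Analysis with Structural Coupling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Sliding-window dynamic functional connectivity (D-FC) analysis
    for regional brain time series: windowed correlation matrices, temporal
    edge statistics (strength and variability), significance- and
    sparsity-based network thresholding, graph-theoretical topology with
    degree-preserving (Maslov-Sneppen) random-network normalization, hub
    identification and persistence, structural-network backbone construction
    from streamline counts, and structure-function coupling tests at the
    connection, global-topology and nodal-topology levels. Includes a
    state-switching multivariate Gaussian generator that produces synthetic
    parcellations, structural networks and BOLD-like series with planted
    homotopic, structural-coupling and hub effects, so the whole pipeline is
    testable end to end without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    graphics,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
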