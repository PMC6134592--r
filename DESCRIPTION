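Package: exocube
Title: Exometabolomics Assertion Datacubes, Compatibility Scores and
    Interaction Webs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for curated exometabolomics (metabolite footprinting)
    assertion data. Stores qualitative observations of how microorganisms
    change the metabolite composition of an environment -- increased,
    decreased, no change, or not investigated, plus detected/not-detected
    calls for the untransformed control -- in a three-dimensional
    organism x metabolite x environment datacube with tab-delimited upload
    files and a single-file SQLite persistence layer. Converts replicate
    control-versus-spent relative-abundance measurements into action
    assertions with log2-fold-change confidence shading, computes
    environmental uptake (EUS) and organismal compatibility scores
    (OCS-FMC competition, OCS-FME exchange) for predicting metabolite
    competition and exchange between co-cultured organisms, renders the
    one-environment / one-organism / one-metabolite slice tables and the
    bipartite organism-metabolite interaction web, and provides seeded
    simulators of datacubes and replicate abundance experiments for
    calibration and testing.
License: MIT
Encoding: UTF-8
Imports:
    DBI,
    RSQLite,
    igraph,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
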