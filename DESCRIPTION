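Package: auxofba
Title: Auxotrophy-Based Simulation and Curation of Genome-Scale Metabolic Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for testing and curating genome-scale metabolic models (GEMs)
    against auxotrophy data. Implements flux balance analysis with a two-step
    knockout-and-compound-rescue procedure, a type-I/type-II misprediction
    taxonomy, curation operators (reaction blocking, gene-protein-reaction rule
    rewriting, reaction and exchange addition, mass-balanced biomass
    pseudoreaction rescaling), the full machine-readable curation set derived
    for the consensus yeast model, systematic gene-by-compound auxotroph
    screening, and deterministic toy-model generators with planted ground truth
    for end-to-end verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    xml2,
    yaml,
    rlang,
    stats,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
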