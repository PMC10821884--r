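Package: fluxtrace
Title: Traceable Management and Flux Balance Analysis of Metabolic Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A desk-scale server for constraint-based metabolic models that
    keeps model files immutable while all user alterations live in versioned
    modification files. Models are stored as SBML (Level 3 with the
    flux-balance-constraints package), spatial projections as Cytoscape CyJson
    view files, and alterations (reaction knockouts, bound changes) as YAML
    modification files carrying author, date, root model and an optional
    parent, so that every intermediate state of a model can be recovered
    (temporal traceability) and any two states compared entry-by-entry
    (differential traceability). A flux balance analysis engine applies the
    effective modification state to the stoichiometric linear program and
    solves it with a bounded-variable simplex method, reporting fluxes plus
    the visual scalars (colour interpolation, edge-width clamping, particle
    debit) used by graphical clients. The store, lineage and solver are
    exposed over an HTTP query API with an action-schema handshake, and
    deterministic toy-network generators make every layer testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    xml2,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
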