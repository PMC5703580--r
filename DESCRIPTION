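Package: chemofba
Title: Steady States of Continuous Cell Cultures from Constraint-Based Metabolic Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Characterizes steady states of chemostat and perfusion cell
    cultures whose intracellular metabolism is a growth-maximizing flux
    balance model with molecular-crowding (enzyme cost) constraints, toxic
    byproduct feedback on growth, and nutrient uptake bounds coupled to the
    bioreactor through the ratio of cell density to dilution rate (the
    inverse cell-specific perfusion rate). Provides a two-stage
    lexicographic flux balance solver, steady-state scans over the coupling
    parameter, washout rate and medium depth computation, metabolic phase
    detection, stability classification and bifurcation diagrams with
    multistable-window and hysteresis detection, and dynamic flux balance
    simulation under arbitrary dilution-rate schedules. Includes an
    analytically solvable overflow-metabolism toy network used as an oracle,
    readers for COBRA-style JSON and SBML Level 3 FBC models with tabular
    annotations, and a synthetic fixture generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
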