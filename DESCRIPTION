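Package: aquaflux
Title: Stopped-Flow Permeability Kinetics and Pore Structure Analysis for
    Plant Aquaporins
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Simulation and estimation tools for functional and structural
    characterization of plant aquaporins (NIP subfamily). Implements the
    stopped-flow osmotic-shock estimation chain (single-exponential fits of
    cell-shrinkage fluorescence signals, osmotic water permeability Pf,
    glycerol permeability Pgly from linear re-swelling slopes, Arrhenius
    activation energies, replicate aggregation and strain comparison by
    Welch t-test), a mechanistic forward model of the shock experiment for
    validation, channel pore-radius profiling on PDB structures by
    largest-inscribed-sphere search with constriction detection and
    residue-level hydropathy ratios, and alignment-based channel-residue
    conservation analysis with ar/R selectivity-filter mutation bookkeeping.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    bio3d,
    deSolve,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
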