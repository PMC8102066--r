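Package: tmdimer
Title: Interface Kinetics and Stoichiometry of Transmembrane Domain Dimers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of G-protein-coupled receptor transmembrane
    domain (TMD) dimerization. Converts coarse-grained dimer trajectories into
    interface microstates via residue-contact labeling, estimates Markov state
    models with implied-timescale validation, aggregates microstates into
    metastable macrostates with PCCA+, computes transition-path-theory reactive
    fluxes between interface classes, and estimates relative free energies from
    steered-pull work samples via Jarzynski's equality. Companion experimental
    modules quantify single-molecule pulldown photobleaching step distributions
    with min-max dimerization normalization, FRET and calcium concentration-
    response curves with four-parameter logistic fits, and chemical-class
    sequence conservation over residue subsets. A seeded synthetic-data module
    generates inputs with known ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    igraph,
    bio3d,
    seqinr,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
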