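Package: sproutgraph
Title: Morphometry of Bead-Sprouting Microvascular Networks
Version: 0.1.0
Authors@R:
    person("Sproutgraph", "Developers", email = "sproutgraph@example.org",
           role = c("aut", "cre"))
Description: Image-analysis toolkit for the fibrin-gel bead-sprouting
    angiogenesis assay. Segments fluorescence projections of endothelial
    cell-coated beads, skeletonizes the sprout mask into an annotated
    node/segment graph, and computes per-bead per-day morphometrics (total
    length and area, sprout width, tip counts, primary branches, branch
    generations, maximal radial spread). Measures bifurcation angles with a
    fixed-arclength arm method and an outward-bisector anastomosis filter,
    fits logistic growth curves and exponential segment-length
    distributions, and ships a ground-truthed synthetic phantom generator
    so the whole pipeline is testable without raw microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
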