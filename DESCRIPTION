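Package: sigmetmap
Title: Integration of Signalling and Metabolic CellDesigner Network Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for integrating a signalling-pathway map layer and a
    genome-scale metabolic map layer drawn in CellDesigner SBML. Reads and
    writes CellDesigner-flavoured SBML with species-alias layout geometry,
    flattens gene-protein-reaction (GPR) rules of a metabolic model into
    protein-reaction catalysis associations, places catalyst protein nodes in
    the vicinity of the reactions they regulate using canvas-clipped Voronoi
    tessellation, in-cell random sampling and K-means clustering, merges map
    layers with identifier re-writing while preserving names and coordinates,
    and quantifies crosstalk between the two layers' gene-set hierarchies via
    shared-protein counting, hypergeometric enrichment with Bonferroni
    correction, and a weighted bipartite crosstalk network. A synthetic map
    generator produces fully specified miniature map/model/gene-set bundles
    with known ground truth for offline testing, and a command-line interface
    wires the stages into a single pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    xml2,
    igraph,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
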