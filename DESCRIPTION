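Package: hicnets
Title: Chromatin Interaction Modules from Hi-C Contact Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers statistically significant intra-chromosomal chromatin
    interactions from sparse Hi-C contact maps using a distance-stratified
    negative binomial model, removes calls falling in contact deserts,
    assembles the surviving interactions into an undirected genomic-bin
    network, and clusters that network into chromatin interaction modules
    scored by connectivity, transitivity and eigenvector centrality.
    Additional components call super-enhancers from H3K27ac peak occupancy
    by ROSE-style stitching and rank-curve elbow thresholding, compare
    module connectivity between two conditions to label condition-specific
    modules, simulate ground-truthed synthetic contact maps and peak sets,
    and draw triangle contact heatmaps with interaction arc plots.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    Matrix,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    tools,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    MASS,
    mclust,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
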