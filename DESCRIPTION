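Package: cloneArch
Title: 3D Clonal Architecture Analysis of Growth-Plate Chondrocytes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies the three-dimensional architecture of multicolor
    lineage-traced chondrocyte clones in the mammalian growth plate from
    nuclear centroid coordinates. Identifies within-clone nearest-neighbour
    doublets by a connectivity-threshold (minimum-spanning-tree bottleneck)
    graph, measures doublet elevation angles in a canonical proximal-distal
    frame to classify complete versus incomplete division-plane rotations,
    derives clone shape and orientation by principal component analysis to
    separate columns from clusters, merges neighbouring clones into
    multiclones, validates nuclear centroids as a proxy for cell centroids
    by mutual-nearest-neighbour matching and correlation of clone-mean
    elevation angles, and computes growth-plate elongation and expansion
    rates from chondro-osseous-junction voxel surfaces. A seeded synthetic
    generator emulates clones built by sequential divisions with
    configurable rotation-angle mixtures, paired cell/nucleus centroids and
    voxelized junction surfaces, so the whole pipeline is testable without
    microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
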