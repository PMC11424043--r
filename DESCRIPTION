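Package: tcstat
Title: Topological Cluster Statistic for Connectivity-Guided Brain Map Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Cluster-extent inference for multi-subject brain statistical maps
    in which suprathreshold nodes are grouped by a topology that combines
    spatial adjacency with a group-consensus anatomical connectivity
    structure. Provides construction of the binary clustering topology from
    individual streamline-count connectomes (consistency index,
    distance-dependent normalization, connectome spatial smoothing,
    density-matched thresholding, union with a mesh or voxel-grid spatial
    structure), one-sample sign-flip permutation inference with family-wise
    error control over cluster extents, a two-dimensional ribbon phantom
    simulator, evaluation utilities (per-node sensitivity, power curves,
    bookmaker informedness with partial AUC, analytic power bounds), and
    anatomical network summarization of significant clusters (connectome
    filtering, atlas downsampling, major-cluster graphs, maximum spanning
    trees).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
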