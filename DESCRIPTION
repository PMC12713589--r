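Package: spineseg
Title: Curvature-Based Segmentation and Morphometry of Dendritic Spines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for automated segmentation of dendritic spines from
    triangulated surface meshes of dendrites. Provides discrete
    differential-geometry operators (cotangent mean curvature, angle-deficit
    Gaussian curvature, Willmore-flow smoothing), voxelization and
    topology-preserving 3D thinning for shaft skeletons, per-vertex feature
    assembly (clipped curvatures, distance-to-skeleton, K-means region
    labels), small multilayer-perceptron vertex classifiers trained with a
    weighted binary cross-entropy loss, connected-component spine detection,
    and per-spine morphometry (neck and head diameter, length, surface area,
    volume). A synthetic spiny-dendrite generator with exact per-vertex
    labels makes the whole pipeline testable without electron-microscopy
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
SystemRequirements: C++17
Config/testthat/edition: 3
RoxygenNote: 7.3.3
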