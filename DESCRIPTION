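Package: pocketgnn
Title: Protein-Ligand Binding Site Prediction with a Point-Cloud Graph
    Neural Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts ligand-binding pockets on protein surfaces. The protein
    surface is sampled as an oriented point cloud carrying 16 per-point
    features (6 learned chemical features from the local atomic environment
    and mean/Gaussian curvature at five spatial scales), voxel-downsampled
    into a fixed-radius graph, and processed by a translation-robust graph
    neural network with an auto-registration offset. High-probability surface
    points are grouped into ranked pockets with OPTICS density clustering.
    Includes pocket-level evaluation metrics (center-center distance, success
    rate, discretized volume overlap, pocket-level F1), a synthetic
    planted-pocket structure generator for end-to-end testing, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
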