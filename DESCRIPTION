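Package: bonewrap
Title: Shrinkwrap Surface Filtering of Bone CT Segmentations for 3D-Printable Fracture Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts a computed-tomography bone segmentation into a thin,
    watertight, evenly walled triangle mesh suitable for fused-deposition 3D
    printing of fracture models. Implements an offset shrinkwrap with
    voxelization-based remeshing, a normal-ray projection step that rescues deep
    concavities such as the acetabular cup, gap deletion that preserves fracture
    lines, and shell solidification. Also provides Hounsfield-threshold
    segmentation with connected-component selection, landmark rigid registration
    with surface-distance validation metrics, synthetic CT phantoms for testing,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    igraph,
    tibble,
    generics,
    ggplot2,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
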