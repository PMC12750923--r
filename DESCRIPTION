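Package: osteosym
Title: Bilateral Bony Symmetry Analysis of Paired Bone Surface Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies three-dimensional bilateral morphological symmetry of
    paired bone surface models (distal femur, patella, proximal tibia). The
    left-side triangle mesh is mirrored in the sagittal plane, registered to
    its right-side counterpart by rigid Coherent Point Drift (CPD), the joint
    region is isolated by an iterative trim-and-register rule, and a nonrigid
    CPD deformation of the right model onto the aligned left model yields
    per-correspondence-point Euclidean distances that are summarised as
    medians, interquartile ranges and 1st-99th percentiles and exported as
    surface heatmaps. Includes STL/PLY mesh input/output, isotropic remeshing
    to a uniform element size, loose-fragment filtering, and a synthetic
    paired-bone generator with known injected asymmetry for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
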