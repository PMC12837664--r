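Package: stenoscan
Title: Coronary Stenosis Grading and Plaque Classification on Straightened
    Vessel Sequences with Selective State-Space Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale implementation of a hierarchical geometric-semantic
    network for assessing coronary artery lesions on straightened
    (curved-planar-reformation) image sequences. The network couples a
    bidirectional selective state-space (Mamba-style) encoder over the
    centerline with distance-biased cross-attention fusion of a volumetric
    stream, decouples plaque texture from lumen geometry via ring-pooled
    spectral fingerprints and texture-guided deformable boundary sampling,
    and learns from mixed-grained labels (per-segment and branch-maximum
    stenosis grades) through dynamic grade prototypes, weak branch-level
    supervision and logical consistency regularisers. Includes a synthetic
    vessel-phantom generator with dual-granularity annotations, a
    reverse-mode automatic-differentiation engine used to train the network
    on the CPU, confusion-matrix evaluation metrics, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
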