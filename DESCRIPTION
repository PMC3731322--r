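Package: nindepth
Title: Depth and Spatial Sensitivity Analysis for Near-Infrared Neuromonitoring
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Voxel-based Monte Carlo simulation of near-infrared photon
    transport through five-tissue head models (scalp, skull, CSF, gray and
    white matter), construction of source-detector spatial sensitivity maps
    (3-point Green's functions) from pairs of fluence distributions, and
    quantification of NIRS sensitivity by tissue class, source-detector
    separation and intracranial depth, including the exponential
    depth-sensitivity regression S(d) = a + b*c^d and its rule-of-thumb
    summary. Ships synthetic layered head phantoms (spheres and slabs) so the
    full analysis runs without external imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    minpack.lm,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
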