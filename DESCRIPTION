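Package: decm
Title: Dynamic Eigenvector Centrality Mapping for Resting-State fMRI
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Voxelwise eigenvector centrality of resting-state fMRI computed
    in a sliding temporal window by matrix-free power iteration on the
    implicit correlation-plus-one connectivity matrix. Includes mask
    construction from gray-matter density and temporal-minimum maps, motion
    confound residualization, dual regression of centrality time series onto
    resting-state network templates, permutation-based group inference with
    threshold-free cluster enhancement and max-statistic family-wise error
    control, group summary curves, a synthetic multi-subject data generator
    with planted network structure, and a file-driven analysis pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    RNifti,
    Rcpp,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
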