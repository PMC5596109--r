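Package: fmica
Title: Hierarchical Feature-Map ICA for Multi-Dataset fMRI Brain Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies brain functional networks at four hierarchical levels
    (subject-specific, intragroup, intragroup-specific and intergroup) from
    multi-dataset fMRI using per-subject spatial independent-component feature
    maps as the only cross-level currency. Provides fixed-point negentropy ICA
    with symmetric decorrelation, Laplace-approximation and ICASSO-stability
    model-order selection, constrained ICA with spatial references (GIG-ICA
    style), z-score statistical parametric maps with cluster-size control, a
    SimTB-style multi-subject fMRI simulator with known ground truth, and
    evaluation utilities (component matching, recovery reports, Welch t-test
    contrasts).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
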