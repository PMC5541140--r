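Package: seegplan
Title: Anatomy-Driven Multiple Trajectory Planning for SEEG Depth Electrodes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes safe, surgically feasible, mutually non-conflicting
    implantation plans for stereo-electroencephalography (SEEG) depth
    electrodes from a segmented head: distance-transform target risk maps
    with spatial priors, iterative-flooding local-minima extraction and
    K-means candidate clustering, hard-constraint filtering with stepwise
    relaxation, cumulative vessel-risk and grey-matter capture scoring of
    every (target, entry) pair, and a depth-first combinatorial search with
    diversity pruning and a max-separation fallback for the joint plan. A
    parameterized head-phantom generator provides fully synthetic inputs
    with verified vessel-free corridors, so the whole pipeline is testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    tools,
    utils,
    Rcpp,
    RNifti,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
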