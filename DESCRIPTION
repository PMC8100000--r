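Package: hippoconn
Title: Seed-Based Hippocampal Functional Connectivity and Subfield Volumetry
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for seed-based resting-state functional connectivity of the
    hippocampus and for hippocampal subfield volumetry. Implements a
    posterior-cingulate-coupled seed-selection algorithm on native-space BOLD
    time series, a physiological-confound regression and temporal/spatial
    filtering chain, correlation-to-t conversion with whole-brain z
    normalization, group-level map thresholding with cluster-extent filtering
    and union ROI definition, intracranial-volume correction and composite
    subfield derivation, asymmetry indices, and the group statistics
    (t-tests, correlations, interaction regression, Benjamini-Hochberg FDR)
    used to compare a clinical group against controls. A synthetic-phantom
    generator with planted hippocampus-PCC coupling makes every stage testable
    without participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    igraph,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
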