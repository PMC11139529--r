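Package: qamskit
Title: Single-Marker Quantitation, Mass Annotation, Network Screening and
    Chemometrics for Herbal Quality Evaluation
Version: 0.1.0
Authors@R:
    person("Qamskit", "Developers", email = "qamskit@example.org",
           role = c("aut", "cre"))
Description: Tools for multicomponent quality evaluation of herbal materials
    quantified by HPLC. Implements quantitative analysis of multicomponents
    by single marker (QAMS) with slope-ratio relative correction factors,
    calibration fitting and full method-validation statistics (recovery,
    precision, repeatability, durability), monoisotopic-mass annotation of
    negative-mode LC-MS peaks, protein-protein interaction centrality
    screening with median thresholds, and a chemometric batch-discrimination
    stack (hierarchical clustering, correlation PCA with composite scoring,
    OPLS-DA with VIP and permutation testing, pooled t-tests). A synthetic
    data generator emulates calibration series, batch peak tables with
    planted group structure, spike-recovery designs, and random interaction
    graphs so the whole pipeline is testable without instrument output.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
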