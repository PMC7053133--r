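Package: subpathSig
Title: Prognostic Subpathway Activity Signatures from Multi-Cohort
    Expression Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Discovery and validation of prognostic functional subpathway
    signatures from multi-cohort transcriptomes. Implements rank-based
    single-sample subpathway activity scoring, distance-bounded subpathway
    mining on pathway graphs, integrated prognostic scoring of features
    across training-cohort combinations with frequency-based signature
    selection, fixed/random-effects meta-analytic validation of pooled
    hazard ratios with heterogeneity diagnostics, and permutation-based
    association of signature activity with drug sensitivity and
    chemotherapy response. Includes a synthetic multi-cohort generator
    with a planted protective subpathway so the full pipeline is testable
    without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    igraph,
    survival,
    S4Vectors,
    SummarizedExperiment,
    yaml
Suggests:
    testthat (>= 3.0.0),
    metafor,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
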