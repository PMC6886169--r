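Package: lncdisnet
Title: Disease-Associated lncRNA Prioritization on a Weighted Functional Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores functional similarity between long non-coding RNAs
    (lncRNAs) by integrating disease, protein and mRNA association evidence.
    Disease functional similarity is computed from disease-gene sets with a
    most-informative-common-ancestor (MICA) semantic correction over a disease
    ontology; per-lncRNA association vectors are imputed by a
    collaborative-filtering MAX rule; cosine and mRNA-overlap similarities are
    combined by a noisy-OR into edge weights of a weighted lncRNA functional
    network. Candidate disease lncRNAs are ranked by random walk with restart,
    and predictions are evaluated with a two-snapshot (version-difference)
    per-disease ROC/AUC protocol. Includes a planted-module synthetic data
    generator so the full pipeline is testable without database downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    igraph,
    jsonlite,
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
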