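Package: scRepurpose
Title: Tumor Subpopulation Discovery and Drug Repurposing from Single-Cell
    Transcriptomes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An integrated workflow from single-cell RNA-seq counts to drug
    treatment suggestions. The package performs quality filtering,
    normalization and Louvain graph clustering with automatic resolution
    selection by subsampling-based robustness scoring; annotates clusters by
    differential expression, local gene-set over-representation and
    correlation against reference expression profiles; scores each cluster's
    prognostic impact in a bulk survival cohort via signature activity scores
    and Kaplan-Meier/log-rank comparison; predicts per-cluster drug
    sensitivity with a kernel-feature latent-factor recommender model trained
    on cell-line drug screens; and proposes minimal drug combinations that
    eliminate the most tumor subpopulations by deconvolving perturbation
    screens and greedy set-cover search. Synthetic-data generators provide a
    download-free, truth-labelled test surface for every step.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    igraph,
    survival,
    pracma,
    jsonlite,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
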