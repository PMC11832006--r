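Package: mrloop
Title: Per-Sample Master Regulator Inference from Bulk Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Identifies master regulators (MRs) that drive gene expression
    changes in individual tumour samples. Starting from a gene-by-sample
    count matrix with designated tumour and reference samples, the pipeline
    calls differentially expressed genes per sample, infers transcription
    factor activities by signed regulon enrichment, traces upstream
    regulators through a signed signalling network by shortest-path causal
    reasoning with permutation tests, selects regulators participating in
    positive feedback loops with a bootstrap cosine criterion, biclusters
    the resulting discrete score matrix, and characterises the regulator
    subnetwork by structural controllability and centrality analysis. A
    synthetic-data generator with planted regulator activities makes every
    stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
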