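Package: mhsgtr
Title: Multi-Omics Cancer Subtyping via Motif High-Order Similarity Graphs
    and Tensor-Regularized Graph Fusion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Integrative clustering of multi-omics sample cohorts (for
    example mRNA expression, DNA methylation and miRNA expression from the
    same tumours). Each omics layer is embedded with a sparse autoencoder
    and a linear self-expressive layer that yields a sample-by-sample
    similarity graph; triangle-motif counts on a thresholded Gaussian-kernel
    graph supply high-order structural information that is blended into a
    hybrid similarity and used to regularize the self-expressive graphs.
    The per-omics graphs are stacked into a third-order tensor whose
    t-SVD tensor nuclear norm couples the omics layers, and a per-sample
    attention mechanism fuses them into a consensus graph that is refined
    with a self-training Kullback-Leibler term and clustered by spectral
    clustering. Includes a synthetic multi-omics generator with planted
    cluster structure, cluster-linked survival and clinical labels, the
    log-rank and clinical-enrichment evaluation statistics, an ablation
    harness comparing first-order, motif and hybrid similarity, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
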