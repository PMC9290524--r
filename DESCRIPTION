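Package: rhizomod
Title: Gene Coexpression Modules and Mycorrhizal Abundance from Root Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Weighted gene coexpression network analysis for field root
    transcriptomes: TPM normalization and filtering, soft-threshold selection
    by scale-free topology fit, topological overlap, module detection and
    merging, module eigengenes and kME connectivity, k-means submodule
    decomposition, GO term enrichment, seeded module extraction from curated
    marker genes, module-environment correlation and regression statistics,
    and quantification of arbuscular-mycorrhizal fungal abundance from rRNA
    reads embedded in mRNA-seq data (read assignment, length normalization,
    Bray-Curtis dissimilarity and non-metric multidimensional scaling). A
    synthetic-data generator with planted module structure provides
    ground-truth benchmarks for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    Biostrings,
    vegan
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    withr
Config/testthat/edition: 3
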